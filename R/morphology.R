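#' Compartmental model morphology
#'
#' A model is a rooted tree of cylindrical compartments. Each compartment has
#' a membrane area `2*pi*r*L`, an intracellular volume `pi*r^2*L`, and an
#' extracellular shell whose volume is a fixed fraction (default 15%) of the
#' intracellular volume. The soma is represented as an equivalent cylinder of
#' equal membrane area. Path distances are measured from the soma centroid to
#' compartment midpoints.
#'
#' @name morphology
NULL

REGIONS <- c("soma", "axon", "apical_proximal", "radiatum_thick_medial",
             "radiatum_thick_distal_or_thin", "lacunosum_moleculare",
             "oriens_proximal", "oriens_distal")

# type codes follow the SWC convention
TYPE_SOMA <- 1L; TYPE_AXON <- 2L; TYPE_BASAL <- 3L; TYPE_APICAL <- 4L

#' Construct a compartmental model from raw cylinders
#'
#' @param length_um,radius_um cylinder dimensions (micrometres), positive.
#' @param parent integer parent index per compartment (`NA` for the root);
#'   parents must precede children.
#' @param type SWC-style type code (1 soma, 2 axon, 3 basal, 4 apical).
#' @param params model parameters ([load_parameters()]).
#' @param shell_frac extracellular shell volume as a fraction of the
#'   intracellular volume (recycled).
#' @return an object of class `ion_model`.
#' @export
new_ion_model <- function(length_um, radius_um, parent, type,
                          params = default_parameters(),
                          shell_frac = params$shell_fraction) {
  n <- length(length_um)
  stopifnot(length(radius_um) == n, length(parent) == n, length(type) == n)
  if (any(radius_um <= 0) || any(length_um <= 0)) {
    stop("compartment radii and lengths must be positive", call. = FALSE)
  }
  if (sum(is.na(parent)) != 1L || !is.na(parent[1])) {
    stop("exactly one root (compartment 1) is required", call. = FALSE)
  }
  if (any(parent[-1] >= seq_len(n)[-1], na.rm = TRUE)) {
    stop("parents must precede children (topological order)", call. = FALSE)
  }
  shell_frac <- rep_len(shell_frac, n)
  geom <- data.frame(
    id = seq_len(n),
    parent = as.integer(parent),
    type = as.integer(type),
    length_um = as.numeric(length_um),
    radius_um = as.numeric(radius_um),
    shell_frac = shell_frac
  )
  geom$area_cm2 <- 2 * pi * geom$radius_um * geom$length_um * 1e-8
  geom$vol_i_cm3 <- pi * geom$radius_um^2 * geom$length_um * 1e-12
  geom$vol_o_cm3 <- geom$shell_frac * geom$vol_i_cm3

  # midpoint path distance; the soma's own extent is collapsed to its centroid
  dist <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- geom$parent[i]
    lp <- if (geom$type[p] == TYPE_SOMA) 0 else geom$length_um[p]
    dist[i] <- dist[p] + (lp + geom$length_um[i]) / 2
  }
  geom$dist_um <- dist
  geom$region <- assign_regions(geom, params)

  model <- structure(
    list(geometry = geom, params = params, mech = NULL, calibration = NULL),
    class = "ion_model"
  )
  recompute_coupling(model)
}

# axial conductances (S) and diffusion couplings to each compartment's parent
recompute_coupling <- function(model) {
  g <- model$geometry
  n <- nrow(g)
  ra <- model$params$physical$axial_resistivity_ohm_cm
  g_ax <- rep(NA_real_, n)
  surf_i <- rep(NA_real_, n); surf_o <- rep(NA_real_, n); dd <- rep(NA_real_, n)
  for (i in seq_len(n)[-1]) {
    p <- g$parent[i]
    half <- function(j) ra * (g$length_um[j] * 1e-4 / 2) /
      (pi * (g$radius_um[j] * 1e-4)^2)
    g_ax[i] <- 1 / (half(i) + half(p))
    rbar <- (g$radius_um[i] + g$radius_um[p]) / 2 * 1e-4
    surf_i[i] <- pi * rbar^2
    surf_o[i] <- 0.5 * (g$shell_frac[i] + g$shell_frac[p]) * surf_i[i]
    dd[i] <- (g$length_um[i] + g$length_um[p]) / 2 * 1e-4
  }
  model$g_axial <- g_ax
  model$diff_surf_i <- surf_i
  model$diff_surf_o <- surf_o
  model$diff_dist <- dd
  model
}

#' Assign layer regions used for synapse densities
#'
#' Apical compartments are classified by path distance (proximal < 150 um;
#' thick medial radiatum 150-300 um when the radius exceeds the trunk
#' threshold; distal/thin radiatum to 400 um; lacunosum-moleculare beyond) and
#' basal compartments by the 100 um proximal oriens boundary. Boundaries are
#' parameters (`params$regions`).
#'
#' @param geom geometry data frame (internal layout).
#' @inheritParams new_ion_model
#' @return character vector of region labels.
#' @export
assign_regions <- function(geom, params) {
  rg <- params$regions
  out <- character(nrow(geom))
  for (i in seq_len(nrow(geom))) {
    out[i] <- switch(
      as.character(geom$type[i]),
      "1" = "soma",
      "2" = "axon",
      "3" = if (geom$dist_um[i] < rg$oriens_proximal_max_um)
        "oriens_proximal" else "oriens_distal",
      { # apical and anything else
        d <- geom$dist_um[i]
        if (d < rg$apical_proximal_max_um) "apical_proximal"
        else if (d < rg$radiatum_medial_max_um &&
                 geom$radius_um[i] >= rg$trunk_radius_um) "radiatum_thick_medial"
        else if (d < rg$radiatum_distal_max_um) "radiatum_thick_distal_or_thin"
        else "lacunosum_moleculare"
      }
    )
  }
  out
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). Contiguous soma
#' points are merged into a single equivalent cylinder; every other point
#' becomes a cylinder from its parent's coordinate with the point's radius.
#'
#' @param path SWC file path.
#' @inheritParams new_ion_model
#' @return an `ion_model`.
#' @export
read_swc <- function(path, params = default_parameters(),
                     shell_frac = params$shell_fraction) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  if (any(raw$r <= 0)) {
    bad <- raw$id[raw$r <= 0][1]
    stop(sprintf("SWC node %d has non-positive radius", bad), call. = FALSE)
  }
  idx <- match(raw$parent, raw$id)
  roots <- which(raw$parent < 0)
  if (length(roots) != 1L) {
    stop("SWC must contain exactly one root node", call. = FALSE)
  }
  if (any(is.na(idx) & raw$parent >= 0)) {
    bad <- raw$id[is.na(idx) & raw$parent >= 0][1]
    stop(sprintf("SWC node %d references a missing parent", bad), call. = FALSE)
  }
  # reachability from root; a cycle or disconnected node fails this walk
  order <- integer(0); seen <- logical(nrow(raw))
  queue <- roots
  children <- split(seq_len(nrow(raw)), factor(idx, levels = seq_len(nrow(raw))))
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    if (seen[i]) stop(sprintf("SWC node %d is part of a cycle", raw$id[i]),
                      call. = FALSE)
    seen[i] <- TRUE; order <- c(order, i)
    queue <- c(queue, children[[i]])
  }
  if (!all(seen)) {
    bad <- raw$id[which(!seen)[1]]
    stop(sprintf("SWC node %d is disconnected from the root", bad), call. = FALSE)
  }
  raw <- raw[order, ]; rownames(raw) <- NULL
  idx <- match(raw$parent, raw$id)

  soma_rows <- which(raw$type == TYPE_SOMA)
  soma_r <- max(raw$r[soma_rows])
  soma_len <- if (length(soma_rows) > 1) {
    sum(vapply(soma_rows[-1], function(i) {
      p <- idx[i]
      sqrt(sum((raw[i, c("x", "y", "z")] - raw[p, c("x", "y", "z")])^2))
    }, numeric(1)))
  } else 2 * soma_r  # sphere -> equal-area cylinder
  soma_len <- max(soma_len, 2 * soma_r)

  len <- c(soma_len); rad <- c(soma_r); par <- c(NA_integer_)
  typ <- c(TYPE_SOMA)
  newid <- rep(NA_integer_, nrow(raw)); newid[soma_rows] <- 1L
  for (i in seq_len(nrow(raw))) {
    if (raw$type[i] == TYPE_SOMA) next
    p <- idx[i]
    l <- sqrt(sum((raw[i, c("x", "y", "z")] - raw[p, c("x", "y", "z")])^2))
    len <- c(len, max(l, 0.05))
    rad <- c(rad, raw$r[i])
    par <- c(par, newid[p])
    typ <- c(typ, if (raw$type[i] %in% c(2L, 3L)) raw$type[i] else TYPE_APICAL)
    newid[i] <- length(len)
  }
  new_ion_model(len, rad, par, typ, params, shell_frac)
}

#' Write a model as an SWC file
#'
#' Coordinates are synthesised (compartments extend along x, with y offsets
#' per branch); geometry round-trips through [read_swc()].
#'
#' @param model an `ion_model`.
#' @param path output file.
#' @export
write_swc <- function(model, path) {
  g <- model$geometry
  n <- nrow(g)
  x <- numeric(n); y <- numeric(n); ang <- numeric(n)
  nkids <- integer(n)
  for (i in seq_len(n)[-1]) {
    p <- g$parent[i]
    nkids[p] <- nkids[p] + 1L
    # each sibling leaves at its own angle so segment lengths are preserved
    ang[i] <- ang[p] + (nkids[p] - 1L) * 0.4
    x[i] <- x[p] + g$length_um[i] * cos(ang[i])
    y[i] <- y[p] + g$length_um[i] * sin(ang[i])
  }
  df <- data.frame(id = g$id, type = g$type, x = x, y = y, z = 0,
                   r = g$radius_um,
                   parent = ifelse(is.na(g$parent), -1L, g$parent))
  lines <- c("# generated by ionshift::write_swc",
             apply(df, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Load a morphology and append an axon
#'
#' @param path SWC file.
#' @param axon_spec list describing the synthetic axon: `n_initial` tapering
#'   initial-segment compartments of `initial_length_um` each, tapering from
#'   `initial_radius_um` to `final_radius_um`, followed by `n_cable`
#'   compartments of `cable_length_um` at `final_radius_um`. `NULL` skips the
#'   axon.
#' @inheritParams new_ion_model
#' @return an `ion_model` with axon compartments appended to the soma.
#' @export
load_morphology <- function(path, axon_spec = default_axon_spec(),
                            params = default_parameters()) {
  model <- read_swc(path, params)
  if (!is.null(axon_spec)) model <- attach_axon(model, axon_spec)
  model
}

#' @rdname load_morphology
#' @export
default_axon_spec <- function() {
  list(n_initial = 5L, initial_length_um = 10, initial_radius_um = 1.0,
       final_radius_um = 0.5, n_cable = 5L, cable_length_um = 30)
}

#' @rdname load_morphology
#' @param model an `ion_model` whose root is the soma.
#' @export
attach_axon <- function(model, axon_spec = default_axon_spec()) {
  g <- model$geometry
  s <- axon_spec
  r_init <- seq(s$initial_radius_um, s$final_radius_um,
                length.out = s$n_initial)
  len <- c(g$length_um, rep(s$initial_length_um, s$n_initial),
           rep(s$cable_length_um, s$n_cable))
  rad <- c(g$radius_um, r_init, rep(s$final_radius_um, s$n_cable))
  n0 <- nrow(g)
  newpar <- c(n0 + seq_len(s$n_initial + s$n_cable)) - 1L
  newpar[1] <- 1L  # first axon compartment hangs off the soma
  par <- c(g$parent, newpar)
  typ <- c(g$type, rep(TYPE_AXON, s$n_initial + s$n_cable))
  new_ion_model(len, rad, par, typ, model$params, g$shell_frac[1])
}

#' Refine the spatial discretization
#'
#' Splits every cylinder into `factor` equal sub-cylinders. Total membrane
#' area, intracellular volume and shell volume are conserved exactly;
#' per-area mechanism densities are preserved where mechanisms are attached.
#'
#' @param model an `ion_model`.
#' @param factor integer >= 1.
#' @return the refined `ion_model`.
#' @export
refine <- function(model, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(model)
  g <- model$geometry
  n <- nrow(g)
  len <- c(); rad <- c(); par <- c(); typ <- c(); src <- c()
  last_piece <- integer(n)  # index of the distal sub-cylinder per original
  for (i in seq_len(n)) {
    k <- if (g$type[i] == TYPE_SOMA) 1L else factor  # keep point-like soma whole
    p0 <- if (is.na(g$parent[i])) NA_integer_ else last_piece[g$parent[i]]
    for (j in seq_len(k)) {
      len <- c(len, g$length_um[i] / k); rad <- c(rad, g$radius_um[i])
      par <- c(par, if (j == 1L) p0 else length(len) - 1L)
      typ <- c(typ, g$type[i]); src <- c(src, i)
    }
    last_piece[i] <- length(len)
  }
  out <- new_ion_model(len, rad, par, typ, model$params, g$shell_frac[src])
  out$geometry$region <- g$region[src]   # regions inherited, not re-derived
  if (!is.null(model$mech)) {
    mech <- model$mech
    for (nm in names(mech)) {
      m <- mech[[nm]]
      mech[[nm]] <- if (is.matrix(m)) m[src, , drop = FALSE] else m[src]
    }
    # synapse counts are re-derived from the conserved conductance density
    mech$gaba_count <- round(mech$gaba_gbar * out$geometry$area_cm2 / 1e-9)
    out$mech <- mech
  }
  out$calibration <- NULL
  if (!is.null(model$calibration)) out <- inherit_calibration(out, model, src)
  out
}

inherit_calibration <- function(out, model, src) {
  cal <- model$calibration
  for (nm in c("nak_imax", "gleak_na", "gleak_k", "gleak_cl",
               "nkcc1_U", "nacax_scale")) {
    cal[[nm]] <- model$calibration[[nm]][src]
  }
  out$calibration <- cal
  out
}

#' Synthetic morphology fixtures
#'
#' Deterministic small morphologies covering every synapse-density region:
#' * `single`: one cylindrical compartment.
#' * `ball_and_stick`: soma plus an unbranched apical cable.
#' * `branched`: soma, trunk, and two thin daughters.
#' * `pyramidal`: a reduced CA1-like cell (soma, tapering apical trunk with
#'   thin oblique and tuft branches, two basal dendrites, axon) whose
#'   compartments populate all labelled layers.
#'
#' @param kind one of `"single"`, `"ball_and_stick"`, `"branched"`,
#'   `"pyramidal"`.
#' @param ... dimension overrides, see the function body for names/defaults.
#' @inheritParams new_ion_model
#' @return an `ion_model`.
#' @export
make_fixture <- function(kind = c("single", "ball_and_stick", "branched",
                                  "pyramidal"),
                         ..., params = default_parameters()) {
  kind <- match.arg(kind)
  dots <- list(...)
  arg <- function(name, default) if (!is.null(dots[[name]])) dots[[name]] else default
  chain <- function(lens, rads, types, from) {
    # returns rows appended to the builder environment
    for (j in seq_along(lens)) {
      b$len <- c(b$len, lens[j]); b$rad <- c(b$rad, rads[j])
      b$par <- c(b$par, from); b$typ <- c(b$typ, types[j])
      from <- length(b$len)
    }
    from
  }
  b <- new.env()
  switch(kind,
    single = {
      b$len <- arg("length_um", 20); b$rad <- arg("radius_um", 10)
      b$par <- NA_integer_; b$typ <- TYPE_SOMA
    },
    ball_and_stick = {
      nseg <- arg("nseg", 8L)
      stick <- arg("stick_length_um", 400)
      b$len <- arg("soma_length_um", 20); b$rad <- arg("soma_radius_um", 10)
      b$par <- NA_integer_; b$typ <- TYPE_SOMA
      chain(rep(stick / nseg, nseg), rep(arg("stick_radius_um", 1), nseg),
            rep(TYPE_APICAL, nseg), 1L)
    },
    branched = {
      b$len <- 20; b$rad <- 10; b$par <- NA_integer_; b$typ <- TYPE_SOMA
      tip <- chain(rep(25, 4), rep(1.5, 4), rep(TYPE_APICAL, 4), 1L)
      ndaught <- arg("daughters", 2L)
      for (d in seq_len(ndaught)) {
        chain(rep(25, 6), rep(0.4, 6), rep(TYPE_APICAL, 6), tip)
      }
    },
    pyramidal = {
      b$len <- 20; b$rad <- 10; b$par <- NA_integer_; b$typ <- TYPE_SOMA
      ntr <- 10L
      trunk_r <- seq(1.8, 0.7, length.out = ntr)
      tip <- 1L
      oblique_at <- integer(0)
      for (j in seq_len(ntr)) {
        tip <- chain(40, trunk_r[j], TYPE_APICAL, tip)
        if (j %in% c(2L, 3L, 4L, 5L, 6L)) oblique_at <- c(oblique_at, tip)
      }
      # thin oblique branches off the proximal/mid trunk (the dominant
      # chloride-loading compartments: small volume, high synapse density)
      for (ob in oblique_at) {
        chain(rep(50, 3), rep(0.35, 3), rep(TYPE_APICAL, 3), ob)
      }
      # tuft branches beyond 400 um
      chain(rep(40, 2), rep(0.4, 2), rep(TYPE_APICAL, 2), tip)
      chain(rep(40, 2), rep(0.4, 2), rep(TYPE_APICAL, 2), tip)
      # basal dendrites
      chain(rep(30, 4), rep(0.8, 4), rep(TYPE_BASAL, 4), 1L)
      chain(rep(30, 4), rep(0.5, 4), rep(TYPE_BASAL, 4), 1L)
      # short axon
      chain(c(10, 10, 30, 30), c(0.8, 0.6, 0.4, 0.4), rep(TYPE_AXON, 4), 1L)
    }
  )
  new_ion_model(b$len, b$rad, b$par, b$typ, params,
                arg("shell_frac", params$shell_fraction))
}

#' Per-compartment morphology summary
#'
#' @param model an `ion_model`.
#' @return a data frame with id, parent, geometry, path distance and region.
#' @export
morphology_summary <- function(model) {
  g <- model$geometry
  data.frame(id = g$id, parent = g$parent, region = g$region,
             length_um = g$length_um, radius_um = g$radius_um,
             area_cm2 = g$area_cm2, vol_i_cm3 = g$vol_i_cm3,
             vol_o_cm3 = g$vol_o_cm3, dist_um = g$dist_um)
}

#' @export
print.ion_model <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<ion_model> %d compartments, total area %.3g cm2\n",
              nrow(g), sum(g$area_cm2)))
  cat("regions:", paste(sprintf("%s=%d", names(table(g$region)),
                                table(g$region)), collapse = ", "), "\n")
  if (!is.null(x$calibration)) cat("calibrated at",
                                   x$calibration$v_rest, "mV\n")
  invisible(x)
}
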