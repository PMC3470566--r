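# generated by ionshift::write_swc
1 1 0 0 0 10 -1
2.0 4.0 25.0 0.0 0.0 1.5 1.0
3.0 4.0 50.0 0.0 0.0 1.5 2.0
4.0 4.0 75.0 0.0 0.0 1.5 3.0
5.0 4.0 100.0 0.0 0.0 1.5 4.0
6.0 4.0 125.0 0.0 0.0 0.4 5.0
7.0 4.0 150.0 0.0 0.0 0.4 6.0
8.0 4.0 175.0 0.0 0.0 0.4 7.0
9.0 4.0 200.0 0.0 0.0 0.4 8.0
10.0 4.0 225.0 0.0 0.0 0.4 9.0
11.0 4.0 250.0 0.0 0.0 0.4 10.0
12.000000 4.000000 123.026525 9.735459 0.000000 0.400000 5.000000
13.00000 4.00000 146.05305 19.47092 0.00000 0.40000 12.00000
14.00000 4.00000 169.07957 29.20638 0.00000 0.40000 13.00000
15.00000 4.00000 192.10610 38.94183 0.00000 0.40000 14.00000
16.00000 4.00000 215.13262 48.67729 0.00000 0.40000 15.00000
17.00000 4.00000 238.15915 58.41275 0.00000 0.40000 16.00000
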