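s01 1 1e+06
s02 1 2e+06
s03 1 3e+06
s04 1 4e+06
s05 1 5e+06
s06 1 6e+06
s07 1 7e+06
s08 1 8e+06
s09 1 9e+06
s10 1 1e+07
s11 2 1e+06
s12 2 2e+06
s13 2 3e+06
s14 2 4e+06
s15 2 5e+06
s16 2 6e+06
s17 2 7e+06
s18 2 8e+06
s19 2 9e+06
s20 2 1e+07
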