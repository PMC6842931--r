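ind01 0 2 NA NA 2 1 0 NA 2 1 1 1 0 1 1 0 1 0 1 1
ind02 0 2 NA NA 2 0 0 NA 0 1 1 0 1 0 1 0 1 0 0 2
ind03 0 2 NA NA 0 2 0 NA 1 1 0 1 2 2 0 1 1 2 0 1
ind04 0 2 NA NA 0 1 0 NA 2 2 2 0 2 2 1 1 0 2 1 0
ind05 0 2 NA NA 2 1 0 NA 1 2 0 1 2 0 0 2 1 2 1 1
ind06 0 2 NA 1 0 1 0 NA 1 1 0 1 0 2 0 0 1 2 1 1
ind07 0 2 2 1 2 1 0 NA 1 1 1 1 2 1 1 1 1 1 2 1
ind08 0 2 1 1 0 2 0 NA 2 2 1 1 1 1 1 2 2 1 1 2
ind09 0 2 1 1 2 2 0 NA 1 0 1 1 1 2 0 1 0 0 1 1
ind10 0 2 1 1 2 0 0 NA 1 0 1 0 0 1 1 1 2 1 1 0
ind11 0 2 1 0 0 0 0 0 2 1 1 1 1 1 2 1 1 0 1 0
ind12 0 2 2 2 0 1 0 0 1 1 0 2 0 1 0 1 2 1 0 0
ind13 0 2 1 1 2 1 0 0 1 0 1 0 1 2 1 0 2 1 2 1
ind14 0 2 0 1 2 0 0 0 0 2 0 0 1 1 2 0 1 1 1 1
ind15 0 2 0 1 0 0 1 0 0 1 0 1 1 2 1 1 0 1 1 1
ind16 0 2 2 1 0 0 0 0 2 0 0 1 1 1 2 2 2 1 2 1
ind17 0 2 1 1 0 1 0 0 1 0 2 0 0 1 1 1 1 0 0 2
ind18 0 2 1 2 0 0 0 0 0 1 1 0 1 0 1 1 1 1 0 1
ind19 0 2 1 1 0 2 0 0 1 2 1 0 0 2 2 2 1 1 0 0
ind20 0 2 1 2 2 1 0 0 1 1 0 2 2 2 1 1 0 0 2 2
ind21 0 2 1 0 0 2 0 0 0 0 2 1 1 1 1 0 1 0 1 0
ind22 0 2 0 1 2 1 0 0 1 0 2 2 2 1 2 1 1 1 1 1
ind23 0 2 1 2 2 0 0 0 1 2 2 2 0 0 1 1 2 2 1 0
ind24 0 2 1 0 2 1 0 0 0 1 1 1 1 0 0 1 0 1 2 1
ind25 0 2 1 1 0 2 0 0 1 1 0 2 1 1 1 1 0 1 1 2
ind26 0 2 1 0 2 1 0 0 0 2 2 0 1 0 1 0 1 1 1 1
ind27 0 2 1 1 2 2 0 0 1 0 1 1 0 1 2 0 0 1 1 1
ind28 0 2 1 2 0 1 0 0 1 1 1 0 2 2 2 2 0 1 0 1
ind29 0 2 1 1 0 0 0 0 1 1 2 1 1 1 1 1 0 1 1 2
ind30 0 2 0 1 2 2 0 0 2 1 1 2 0 1 0 1 1 1 1 1
ind31 0 2 1 1 2 1 0 0 0 2 1 0 0 0 2 0 0 2 1 0
ind32 0 2 1 0 0 2 0 0 1 1 1 1 2 2 0 0 2 0 2 2
ind33 0 2 2 2 0 1 0 0 2 0 1 1 2 1 1 2 2 2 0 0
ind34 0 2 0 2 0 1 0 0 0 1 2 0 1 0 1 2 1 1 1 0
ind35 0 2 0 2 2 1 0 0 1 1 2 1 1 1 0 2 2 1 2 0
ind36 0 2 1 1 2 2 0 0 2 1 0 2 1 1 1 2 1 2 2 2
ind37 0 2 2 0 0 0 0 0 2 0 0 1 0 0 1 1 1 1 1 1
ind38 0 2 2 0 2 1 0 0 2 0 2 1 0 0 1 0 1 2 2 2
ind39 0 2 2 0 2 1 0 0 1 1 1 1 1 1 1 1 1 1 0 1
ind40 0 2 1 1 0 1 0 0 1 1 2 2 1 0 2 2 1 0 0 1
ind41 0 2 0 1 0 1 0 0 2 1 0 2 1 1 2 0 2 2 2 2
ind42 0 2 0 1 0 1 0 0 2 2 1 1 2 1 0 2 0 0 1 1
ind43 0 2 0 1 0 0 0 0 0 1 1 2 2 1 2 2 2 1 1 1
ind44 0 2 2 0 2 1 0 0 1 0 1 1 1 1 0 1 0 1 1 1
ind45 0 2 1 1 2 2 0 0 0 1 1 1 2 2 1 1 1 2 1 1
ind46 0 2 2 1 2 1 0 0 1 2 1 1 1 1 1 1 1 2 1 2
ind47 0 2 1 1 2 0 0 0 1 2 1 2 1 2 2 1 2 0 2 1
ind48 0 2 1 0 0 1 0 0 1 1 1 1 1 1 1 1 1 0 0 2
ind49 0 2 0 0 2 2 0 0 0 2 1 1 1 1 0 1 1 1 0 0
ind50 0 2 2 0 0 1 0 0 1 1 2 2 1 0 1 1 1 1 2 1
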