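group,ref,dev,count
total,WAKE,WAKE,3019
total,WAKE,SLEEP,5525
total,SLEEP,WAKE,3238
total,SLEEP,SLEEP,27786
no_sdis,WAKE,WAKE,1305
no_sdis,WAKE,SLEEP,2117
no_sdis,SLEEP,WAKE,1528
no_sdis,SLEEP,SLEEP,13018
sdis,WAKE,WAKE,1714
sdis,WAKE,SLEEP,3408
sdis,SLEEP,WAKE,1710
sdis,SLEEP,SLEEP,14786
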