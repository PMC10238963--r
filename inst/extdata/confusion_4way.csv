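group,ref,dev,count
total,WAKE,WAKE,3019
total,WAKE,LIGHT,3957
total,WAKE,DEEP,1020
total,WAKE,REM,548
total,LIGHT,WAKE,2236
total,LIGHT,LIGHT,11366
total,LIGHT,DEEP,3468
total,LIGHT,REM,2274
total,DEEP,WAKE,537
total,DEEP,LIGHT,2653
total,DEEP,DEEP,1775
total,DEEP,REM,494
total,REM,WAKE,465
total,REM,LIGHT,4044
total,REM,DEEP,519
total,REM,REM,1193
no_sdis,WAKE,WAKE,1305
no_sdis,WAKE,LIGHT,1630
no_sdis,WAKE,DEEP,272
no_sdis,WAKE,REM,215
no_sdis,LIGHT,WAKE,872
no_sdis,LIGHT,LIGHT,5142
no_sdis,LIGHT,DEEP,1438
no_sdis,LIGHT,REM,1055
no_sdis,DEEP,WAKE,422
no_sdis,DEEP,LIGHT,1469
no_sdis,DEEP,DEEP,982
no_sdis,DEEP,REM,209
no_sdis,REM,WAKE,234
no_sdis,REM,LIGHT,1945
no_sdis,REM,DEEP,263
no_sdis,REM,REM,515
sdis,WAKE,WAKE,1714
sdis,WAKE,LIGHT,2327
sdis,WAKE,DEEP,748
sdis,WAKE,REM,333
sdis,LIGHT,WAKE,1364
sdis,LIGHT,LIGHT,6224
sdis,LIGHT,DEEP,2030
sdis,LIGHT,REM,1219
sdis,DEEP,WAKE,115
sdis,DEEP,LIGHT,1184
sdis,DEEP,DEEP,793
sdis,DEEP,REM,285
sdis,REM,WAKE,231
sdis,REM,LIGHT,2099
sdis,REM,DEEP,256
sdis,REM,REM,678
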