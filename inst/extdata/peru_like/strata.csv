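"sex","age_lo","age_hi","population"
"male",35,39,1183978
"male",40,44,911106
"male",45,49,701021
"male",50,54,539298
"male",55,59,414820
"male",60,64,319024
"male",65,69,245311
"male",70,74,188599
"male",75,79,144974
"male",80,84,111420
"male",85,89,85617
"male",90,94,65777
"male",95,104,50526
"female",35,39,1232303
"female",40,44,970696
"female",45,49,764528
"female",50,54,602073
"female",55,59,474080
"female",60,64,373252
"female",65,69,293834
"female",70,74,231288
"female",75,79,182035
"female",80,84,143254
"female",85,89,112723
"female",90,94,88690
"female",95,104,69774
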