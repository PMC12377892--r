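"sex","age_lo","age_hi","prev_current","prev_former","prev_never"
"male",35,39,0.126506641190172,0.0726682645771556,0.800825094232672
"male",40,44,0.126506641190172,0.109002396865733,0.764490961944094
"male",45,49,0.120756339317892,0.145336529154311,0.733907131527797
"male",50,54,0.120756339317892,0.181670661442889,0.697572999239219
"male",55,59,0.115006037445611,0.208921260659322,0.676072701895067
"male",60,64,0.109255735573331,0.227088326803611,0.663655937623058
"male",65,69,0.10350543370105,0.236171859875756,0.660322706423194
"male",70,74,0.0977551318287694,0.236171859875756,0.666073008295475
"male",75,79,0.0920048299564889,0.227088326803611,0.6809068432399
"male",80,84,0.0805042262119278,0.218004793731467,0.701490980056605
"male",85,89,0.0690036224673667,0.208921260659322,0.722075116873311
"male",90,94,0.0575030187228055,0.199837727587178,0.742659253690017
"male",95,104,0.0460024149782444,0.181670661442889,0.772326923578867
"female",35,39,0.0286247615637886,0.0284035506340058,0.942971687802206
"female",40,44,0.0286247615637886,0.0426053259510086,0.928769912485203
"female",45,49,0.0273236360381619,0.0568071012680115,0.915869262693827
"female",50,54,0.0273236360381619,0.0710088765850144,0.901667487376824
"female",55,59,0.0260225105125351,0.0816602080727666,0.892317281414698
"female",60,64,0.0247213849869083,0.088761095731268,0.886517519281824
"female",65,69,0.0234202594612816,0.0923115395605187,0.8842682009782
"female",70,74,0.0221191339356548,0.0923115395605187,0.885569326503826
"female",75,79,0.0208180084100281,0.088761095731268,0.890420895858704
"female",80,84,0.0182157573587746,0.0852106519020173,0.896573590739208
"female",85,89,0.0156135063075211,0.0816602080727666,0.902726285619712
"female",90,94,0.0130112552562676,0.0781097642435159,0.908878980500217
"female",95,104,0.010409004205014,0.0710088765850144,0.918582119209972
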