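"sex","age_lo","age_hi","hazard","residual_le"
"male",35,39,0.00296326212830091,35.9527894486309
"male",40,44,0.00453257736240039,31.4596781707418
"male",45,49,0.00693298690991074,27.1351501253006
"male",50,54,0.0106046303570511,23.0222254887599
"male",55,59,0.0162207409982168,19.1681258347636
"male",60,64,0.0248110900307134,15.6212871927891
"male",65,69,0.0379508056123848,12.4269206062914
"male",70,74,0.0580491886832109,9.62149844905528
"male",75,79,0.0887914828790712,7.22712528665097
"male",80,84,0.135814601559532,5.24728522383825
"male",85,89,0.207740713395859,3.66575427916911
"male",90,94,0.317758204984342,2.45132819278313
"male",95,104,0.486039906113482,1.58541027798028
"female",35,39,0.00225207921750869,38.9284746834692
"female",40,44,0.0034447587954243,34.3467049538916
"female",45,49,0.00526907005153217,29.9087832639828
"female",50,54,0.00805951907135883,25.6541022989062
"female",55,59,0.0123277631586448,21.6274350544534
"female",60,64,0.0188564284233422,17.8768780762042
"female",65,69,0.0288426122654124,14.4503489635035
"female",70,74,0.0441173833992403,11.3907195328638
"female",75,79,0.0674815269880941,8.7301856779122
"female",80,84,0.103219097185244,6.48513309641276
"female",85,89,0.157882942180853,4.65352289227686
"female",90,94,0.2414962357881,3.21888608334975
"female",95,104,0.369390328646246,2.18220966713855
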