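well_id,iptg_uM,dox_ng_ml,replicate,fsc,ssc,green,red
nf_example,25,5000,r1,70987.3386763525,80210.0877655419,503.52603161804,502.275188032961
nf_example,25,5000,r1,38892.7444240583,38608.1705728747,293.827159705083,420.055669951593
nf_example,25,5000,r1,61129.7078263052,53388.1952109022,524.453855599382,391.871539910202
nf_example,25,5000,r1,46180.9336880626,55521.2471382328,452.74203910058,649.371124246259
nf_example,25,5000,r1,48520.372032286,47322.7952331683,408.000415474409,344.64573265132
nf_example,25,5000,r1,62402.8647477245,40300.206653392,358.967006311942,357.771714101552
nf_example,25,5000,r1,59188.2026627629,62693.9372911502,535.79704362947,450.97880483184
nf_example,25,5000,r1,58179.5185969466,56200.549038979,365.369524426093,350.809905169942
nf_example,25,5000,r1,63850.2833845081,90935.9141492365,390.481986282503,534.963723899815
nf_example,25,5000,r1,36137.9445763144,33810.9709084813,434.069406368049,386.766613494768
nf_example,25,5000,r1,51315.3698323456,52839.8456675345,462.597899525636,443.682367649028
nf_example,25,5000,r1,56674.0164449834,66203.529069626,540.424909701624,671.375719283225
nf_example,25,5000,r1,36849.2691760298,29109.4392411402,331.025560255023,289.953205144627
nf_example,25,5000,r1,44832.9091326448,41268.4383018714,413.968949959908,344.113890147483
nf_example,25,5000,r1,47529.6262355713,41953.1891694306,369.640174938925,314.408782106971
nf_example,25,5000,r1,52392.6397892302,47603.2780359056,546.973329177562,411.874192516803
nf_example,25,5000,r1,69953.1320410947,30926.6461539691,358.471544763514,342.072811004848
nf_example,25,5000,r1,25440.8213783451,35031.1758065992,285.451250731703,402.746452376931
nf_example,25,5000,r1,31912.1911980388,30556.223463315,282.454469370565,210.411502746027
nf_example,25,5000,r1,65356.4616594523,82610.6201952255,556.530780525094,453.385055217188
nf_example,25,5000,r1,66136.1614731645,55992.5365633889,328.984718868314,309.060347067613
nf_example,25,5000,r1,38959.8301620241,28620.4308251478,304.068711256543,230.664840081645
nf_example,25,5000,r1,62431.2245558991,49695.5049954731,355.551297044695,371.129936425209
nf_example,25,5000,r1,43177.2226682399,53275.1510600236,490.707264800101,385.765761026874
nf_example,25,5000,r1,88727.8065191486,79357.1268524294,539.354591268419,554.144608933776
nf_example,25,5000,r1,40826.8764620897,47373.6761423314,380.918779309642,336.647855251835
nf_example,25,5000,r1,45519.7537877182,43035.6082929398,363.410978296951,356.792233172743
nf_example,25,5000,r1,30743.0757695179,41897.5750220064,316.383478930375,216.09335398842
nf_example,25,5000,r1,55026.3120606969,55232.9248631846,400.370678172067,338.288170160406
nf_example,25,5000,r1,64915.8349789861,43952.0935445167,315.01797915549,392.050511648421
nf_example,25,5000,r1,86901.3176480374,80183.5713765279,494.257605522307,446.965210064163
nf_example,25,5000,r1,44807.8266239011,49992.4217404018,429.648042994829,437.870500815199
nf_example,25,5000,r1,64358.9981594469,53150.6927796258,479.30491899798,424.781920066186
nf_example,25,5000,r1,60243.1213185292,33498.3660935119,355.503675493208,397.567307819548
nf_example,25,5000,r1,51864.5187770903,53498.8912433481,369.395425682981,508.813901841763
nf_example,25,5000,r1,36996.9968830032,46179.8227030794,282.595405529364,244.428960044469
nf_example,25,5000,r1,41820.998224427,29373.0205301285,353.794682040844,368.547409370221
nf_example,25,5000,r1,49598.1438734273,41861.8052626951,344.194455785908,396.830159562432
nf_example,25,5000,r1,46033.884279775,27482.8389749448,266.536484508756,247.381417914796
nf_example,25,5000,r1,57683.1641654813,67076.170680499,379.57109500134,363.387162315319
nf_example,25,5000,r1,54979.5005408833,67660.4560219119,468.674531002733,378.368766646131
nf_example,25,5000,r1,44589.1441856994,50641.1749769918,341.751497930224,348.955428477787
nf_example,25,5000,r1,61893.6276118646,74560.815428839,479.403473142583,454.735805021337
nf_example,25,5000,r1,40169.5761851205,37695.9895643087,362.899162214589,374.306518272482
nf_example,25,5000,r1,38510.4467267161,49250.0899375525,259.341749742222,265.98532541022
nf_example,25,5000,r1,66436.6191662783,47462.6652659888,415.1342513613,566.163719128775
nf_example,25,5000,r1,48362.1095522172,47205.2697452837,312.803676896177,343.229071127781
nf_example,25,5000,r1,65159.7178420234,58484.3379682082,448.880172674081,465.135466526479
nf_example,25,5000,r1,44530.9540490576,44327.1545318066,415.6293642761,419.638572752566
nf_example,25,5000,r1,66458.4385611793,61534.2062639287,466.370822415229,352.12024898028
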