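(((bg_017:0.2171290363,bg_022:0.1723973285):0.7121108761,((bg_032:0.02481315192,bg_002:1.530585403):0.5893800525,(bg_020:1.380203125,(((bg_021:0.8013496073,bg_014:0.7438120623):3.87745219,(((bg_003:0.4073074977,bg_027:0.06347058093):0.9703024216,(bg_029:0.2945598851,bg_009:1.385009423):1.204446852):0.8074504043,bg_026:0.8961515454):1.033125855):1.300003739,((syn_up:0.9350347584,bg_025:0.1415436541):0.04870318148,(bg_028:1.115514401,(bg_001:1.451856952,bg_011:1.923922017):0.332526268):0.5890070768):1.280832294):0.2006710983):1.026790097):0.7720702625):1.914220281,((((bg_005:0.6304111853,proch_bimodal:2.188311128):0.7605755989,bg_007:0.5906493519):0.04294892042,((bg_018:1.41909646,(((bg_010:1.311336124,((bg_015:0.4840904032,(bg_030:1.519100109,sar11_down:1.627458578):0.5358915711):1.9110412,bg_006:0.01188187813):0.5309229358):0.2697593216,bg_016:2.326816337):1.118977818,bg_004:0.1387707768):1.132586464):1.759059055,cosmo_flat:3.278212868):0.1221162717):0.6893447665,(((bg_008:1.092537889,bg_019:0.6569166468):0.006151817316,((((bg_012:0.3640500172,bg_035:1.019879678):2.456452332,bg_034:0.9174520931):1.481912104,(bathy_mid:0.3712863578,bg_023:0.2342228463):4.382141459):0.1243210719,(bg_031:2.101087445,bg_024:0.005780430263):1.920586864):0.439886949):1.060361951,(bg_013:0.07571971789,bg_033:1.852720341):0.3187434911):0.3072114633):0.6751960414);
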