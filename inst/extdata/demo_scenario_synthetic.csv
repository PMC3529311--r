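country,quintile,u5mr,coverage,births,cfr,cause:pneumonia,cause:diarrhoea,cause:malaria,cause:preterm,cause:asphyxia,cause:congenital,cause:injury,cause:other,overall_u5mr
Nigeria,1,87,0.45,1260000,0.00218015606161729,0.171154330282892,0.136943121180407,0.0860187818276523,0.158470057809745,0.113814014657117,0.0551780740841284,0.0422483654615386,0.236173254696521,189
Nigeria,2,129,0.35,1260000,0.00592992521525305,0.194912170301467,0.155952121766433,0.106543041430137,0.134497962252602,0.105061831512555,0.0412870564785126,0.034382545879424,0.227363270378869,189
Nigeria,3,165,0.25,1260000,0.0131613170317251,0.214399126218977,0.171543924563581,0.125944250629417,0.114989331410594,0.0965286015661803,0.0316848723395441,0.0283560200115277,0.216553873260178,189
Nigeria,4,212,0.15,1260000,0.0311488612840622,0.237672899431815,0.190165616110286,0.153376449889799,0.0917342083661364,0.0845967082449162,0.0219528145369841,0.0215827709719974,0.198918532448065,189
Nigeria,5,219,0.08,1260000,0.0345344013217402,0.240873128017945,0.192726166523186,0.157633127485033,0.0885237037481015,0.0827869429497829,0.0207442760396862,0.0206821364675301,0.196030518768734,189
Egypt,1,18.9,0.35,380000,0.000664926176789482,0.132637193977774,0.106124988470379,0.0581727793165486,0.197812089272663,0.12397966199575,0.0844886778960266,0.0564535138618477,0.240331095209011,36
Egypt,2,27.2,0.4,380000,0.000867661751114092,0.137225423199772,0.109796098802867,0.0611925223613814,0.193103245841554,0.123054211037304,0.0804491251091811,0.0546541417412319,0.240525231906708,36
Egypt,3,32.2,0.38,380000,0.0010170193619447,0.140010829208397,0.112024743511682,0.0630620883919363,0.190246342358023,0.122452080162538,0.0780788935362806,0.0535769946208111,0.240548028210331,36
Egypt,4,36.1,0.3,380000,0.00115009137933051,0.142193504693836,0.113771134578773,0.0645466900754221,0.188008812939192,0.121959477640013,0.0762630721683701,0.0527407730760869,0.240516534828307,36
Egypt,5,49,0.274,380000,0.00171500204508992,0.149466775064656,0.119590586205401,0.0696215487404569,0.180561985313655,0.120190036513343,0.0704620401881554,0.0500025561820061,0.240104471792326,36
Bangladesh,1,43,0.45,680000,0.00113791261590712,0.146074490160218,0.116876368680322,0.067229806491706,0.184033296076187,0.121039470898272,0.0731210800655556,0.0512705594806953,0.240354928147044,61
Bangladesh,2,62,0.4,680000,0.0020741526103004,0.156859674909947,0.125505755150965,0.0749897633307123,0.17301038390989,0.118196868961887,0.0649327172979232,0.0472924950219601,0.239212341416716,61
Bangladesh,3,83,0.3,680000,0.00390325423088994,0.168866444629252,0.135112549895441,0.0841926928333411,0.160791442015251,0.114561080399609,0.0566622460258382,0.0430390625205414,0.236774481680726,61
Bangladesh,4,85,0.28,680000,0.00413524970894807,0.170010551826734,0.136027967053332,0.0851028482692421,0.159630298096,0.114189631963882,0.0559165558125088,0.0426428878847738,0.236479259093527,61
Bangladesh,5,86,0.27,680000,0.00425553194701463,0.170582488695289,0.136485582234721,0.085560094131288,0.159050058243664,0.114002341127786,0.055546415380096,0.0424454186881338,0.236327601499022,61
Cambodia,1,30,0.5,74000,0.00109950298610495,0.138783394133117,0.111042654481406,0.0622348045607536,0.191505092719962,0.122721112398772,0.0791159424182767,0.0540502625766078,0.240546736711105,54
Cambodia,2,49,0.4,74000,0.00185025021785534,0.149466775064656,0.119590586205401,0.0696215487404569,0.180561985313655,0.120190036513343,0.0704620401881554,0.0500025561820061,0.240104471792326,54
Cambodia,3,68,0.3,74000,0.003067232065827,0.160285695166733,0.128246964832403,0.0775527087233321,0.169517779944449,0.117208900576716,0.0624869551743001,0.0460605952535384,0.238640400328528,54
Cambodia,4,83,0.2,74000,0.00449750488511711,0.168866444629252,0.135112549895441,0.0841926928333411,0.160791442015251,0.114561080399609,0.0566622460258382,0.0430390625205414,0.236774481680726,54
Cambodia,5,90,0.15,74000,0.00534130326949209,0.172869152274372,0.138315175719687,0.0874034681382226,0.156731627402429,0.113242887979092,0.0540838144701893,0.0416597303463888,0.235694143669619,54
Peru,1,9,0.6,124000,0.000327670671316189,0.127230057008394,0.101798657889009,0.0547072871161156,0.203363886813485,0.12496040413837,0.0894783700119201,0.0586153683204811,0.239845968702226,27
Peru,2,24,0.5,124000,0.000554727952664962,0.135450965680035,0.108376328991883,0.0600159102513523,0.194923991992944,0.123422039536483,0.081991017446321,0.0553462938201029,0.240473452280879,27
Peru,3,24,0.45,124000,0.000554727952664962,0.135450965680035,0.108376328991883,0.0600159102513523,0.194923991992944,0.123422039536483,0.081991017446321,0.0553462938201029,0.240473452280879,27
Peru,4,33,0.35,124000,0.00075864181945086,0.140457866205905,0.112382424451572,0.0633647402426784,0.189787980909915,0.12235266349737,0.0777040639538289,0.0534051700739547,0.240545090664777,27
Peru,5,59,0.25,124000,0.00183480235144993,0.155149393847685,0.124137333876582,0.0737284304529049,0.174755610070704,0.118674978587487,0.0661806738160295,0.0479130775072567,0.239460501841352,27
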