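# Quadrature-mirror filter coefficients for the supported mother wavelets.
# Orthogonal families (db, sym, coif) and the spline biorthogonal family
# (bior); bior1.1 coincides with the Haar wavelet.  dec_* are the analysis
# filters, rec_* the synthesis filters of the two-channel filter bank.

.wavelet_registry <- list(
  "db2" = list(
    dec_lo = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.83651630373780794, -0.22414386804201339, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.22414386804201339, 0.83651630373780794, -0.48296291314453416),
    orthogonal = TRUE
  ),
  "db3" = list(
    dec_lo = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458, 0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
    dec_hi = c(-0.33267055295008263, 0.80689150931109255, -0.45987750211849154, -0.13501102001025458, 0.085441273882026658, 0.035226291885709533),
    rec_lo = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154, -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
    rec_hi = c(0.035226291885709533, 0.085441273882026658, -0.13501102001025458, -0.45987750211849154, 0.80689150931109255, -0.33267055295008263),
    orthogonal = TRUE
  ),
  "db4" = list(
    dec_lo = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309, -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
    dec_hi = c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892, -0.027983769416859854, 0.18703481171909309, 0.030841381835560764, -0.032883011666885197, -0.010597401785069032),
    rec_lo = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.032883011666885197, 0.030841381835560764, 0.18703481171909309, -0.027983769416859854, -0.63088076792985892, 0.71484657055291567, -0.23037781330889651),
    orthogonal = TRUE
  ),
  "db5" = list(
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744, 0.077571493840045719, -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.72430852843777294, 0.60382926979718965, 0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.60382926979718965, -0.72430852843777294, 0.13842814590132074, 0.24229488706638203, -0.032244869584638375, -0.077571493840045719, -0.0062414902127982744, 0.012580751999081999, 0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294, 0.13842814590132074, -0.24229488706638203, -0.032244869584638375, 0.077571493840045719, -0.0062414902127982744, -0.012580751999081999, 0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.0062414902127982744, -0.077571493840045719, -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.72430852843777294, 0.60382926979718965, -0.16010239797419293),
    orthogonal = TRUE
  ),
  "db6" = list(
    dec_lo = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613, -0.03158203931748603, 0.027522865530305727, 0.097501605587323043, -0.12976686756726194, -0.22626469396543983, 0.31525035170919763, 0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
    dec_hi = c(-0.11154074335010947, 0.49462389039845306, -0.75113390802109536, 0.31525035170919763, 0.22626469396543983, -0.12976686756726194, -0.097501605587323043, 0.027522865530305727, 0.03158203931748603, 0.00055384220116149613, -0.0047772575109455108, -0.0010773010853084796),
    rec_lo = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536, 0.31525035170919763, -0.22626469396543983, -0.12976686756726194, 0.097501605587323043, 0.027522865530305727, -0.03158203931748603, 0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
    rec_hi = c(-0.0010773010853084796, -0.0047772575109455108, 0.00055384220116149613, 0.03158203931748603, 0.027522865530305727, -0.097501605587323043, -0.12976686756726194, 0.22626469396543983, 0.31525035170919763, -0.75113390802109536, 0.49462389039845306, -0.11154074335010947),
    orthogonal = TRUE
  ),
  "sym2" = list(
    dec_lo = c(-0.12940952255092145, 0.22414386804185735, 0.83651630373746899, 0.48296291314469025),
    dec_hi = c(-0.48296291314469025, 0.83651630373746899, -0.22414386804185735, -0.12940952255092145),
    rec_lo = c(0.48296291314469025, 0.83651630373746899, 0.22414386804185735, -0.12940952255092145),
    rec_hi = c(-0.12940952255092145, -0.22414386804185735, 0.83651630373746899, -0.48296291314469025),
    orthogonal = TRUE
  ),
  "sym3" = list(
    dec_lo = c(0.035226291882100656, -0.085441273882241486, -0.13501102001039084, 0.45987750211933132, 0.80689150931333875, 0.33267055295095688),
    dec_hi = c(-0.33267055295095688, 0.80689150931333875, -0.45987750211933132, -0.13501102001039084, 0.085441273882241486, 0.035226291882100656),
    rec_lo = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132, -0.13501102001039084, -0.085441273882241486, 0.035226291882100656),
    rec_hi = c(0.035226291882100656, 0.085441273882241486, -0.13501102001039084, -0.45987750211933132, 0.80689150931333875, -0.33267055295095688),
    orthogonal = TRUE
  ),
  "sym4" = list(
    dec_lo = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545, 0.80373875180591614, 0.29785779560527736, -0.099219543576847216, -0.012603967262037833, 0.032223100604042702),
    dec_hi = c(-0.032223100604042702, -0.012603967262037833, 0.099219543576847216, 0.29785779560527736, -0.80373875180591614, 0.49761866763201545, 0.02963552764599851, -0.075765714789273325),
    rec_lo = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216, 0.29785779560527736, 0.80373875180591614, 0.49761866763201545, -0.02963552764599851, -0.075765714789273325),
    rec_hi = c(-0.075765714789273325, 0.02963552764599851, 0.49761866763201545, -0.80373875180591614, 0.29785779560527736, 0.099219543576847216, -0.012603967262037833, -0.032223100604042702),
    orthogonal = TRUE
  ),
  "sym5" = list(
    dec_lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936, 0.72340769040242059, 0.63397896345821192, 0.016602105764522319, -0.17532808990845047, -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047, 0.016602105764522319, -0.63397896345821192, 0.72340769040242059, -0.1993975339773936, -0.039134249302383094, -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.016602105764522319, 0.63397896345821192, 0.72340769040242059, 0.1993975339773936, -0.039134249302383094, 0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936, 0.72340769040242059, -0.63397896345821192, 0.016602105764522319, 0.17532808990845047, -0.021101834024758855, -0.019538882735286728),
    orthogonal = TRUE
  ),
  "sym6" = list(
    dec_lo = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057, -0.048311742585632998, 0.49105594192674662, 0.787641141030194, 0.3379294217276218, -0.072637522786462516, -0.021060292512300564, 0.044724901770665779, 0.0017677118642428036, -0.007800708325034148),
    dec_hi = c(0.007800708325034148, 0.0017677118642428036, -0.044724901770665779, -0.021060292512300564, 0.072637522786462516, 0.3379294217276218, -0.787641141030194, 0.49105594192674662, 0.048311742585632998, -0.11799011114819057, -0.0034907120842174702, 0.015404109327027373),
    rec_lo = c(-0.007800708325034148, 0.0017677118642428036, 0.044724901770665779, -0.021060292512300564, -0.072637522786462516, 0.3379294217276218, 0.787641141030194, 0.49105594192674662, -0.048311742585632998, -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
    rec_hi = c(0.015404109327027373, -0.0034907120842174702, -0.11799011114819057, 0.048311742585632998, 0.49105594192674662, -0.787641141030194, 0.3379294217276218, 0.072637522786462516, -0.021060292512300564, -0.044724901770665779, 0.0017677118642428036, 0.007800708325034148),
    orthogonal = TRUE
  ),
  "coif1" = list(
    dec_lo = c(-0.015655728135791993, -0.07273261951252645, 0.38486484686485778, 0.85257202021160039, 0.33789766245748182, -0.07273261951252645),
    dec_hi = c(0.07273261951252645, 0.33789766245748182, -0.85257202021160039, 0.38486484686485778, 0.07273261951252645, -0.015655728135791993),
    rec_lo = c(-0.07273261951252645, 0.33789766245748182, 0.85257202021160039, 0.38486484686485778, -0.07273261951252645, -0.015655728135791993),
    rec_hi = c(-0.015655728135791993, 0.07273261951252645, 0.38486484686485778, -0.85257202021160039, 0.33789766245748182, 0.07273261951252645),
    orthogonal = TRUE
  ),
  "coif2" = list(
    dec_lo = c(-0.00072054944552034698, -0.0018232088709110323, 0.0056114348193688343, 0.02368017194684777, -0.059434418646431092, -0.076488599078280761, 0.41700518442323908, 0.81272363544941351, 0.38611006682276289, -0.067372554723725595, -0.041464936786871777, 0.016387336463203641),
    dec_hi = c(-0.016387336463203641, -0.041464936786871777, 0.067372554723725595, 0.38611006682276289, -0.81272363544941351, 0.41700518442323908, 0.076488599078280761, -0.059434418646431092, -0.02368017194684777, 0.0056114348193688343, 0.0018232088709110323, -0.00072054944552034698),
    rec_lo = c(0.016387336463203641, -0.041464936786871777, -0.067372554723725595, 0.38611006682276289, 0.81272363544941351, 0.41700518442323908, -0.076488599078280761, -0.059434418646431092, 0.02368017194684777, 0.0056114348193688343, -0.0018232088709110323, -0.00072054944552034698),
    rec_hi = c(-0.00072054944552034698, 0.0018232088709110323, 0.0056114348193688343, -0.02368017194684777, -0.059434418646431092, 0.076488599078280761, 0.41700518442323908, -0.81272363544941351, 0.38611006682276289, 0.067372554723725595, -0.041464936786871777, -0.016387336463203641),
    orthogonal = TRUE
  ),
  "coif3" = list(
    dec_lo = c(-3.4599773197272781e-05, -7.0983302506379004e-05, 0.00046621695982040288, 0.0011175187708306303, -0.0025745176881367972, -0.0090079761367306242, 0.015880544863669452, 0.034555027573297738, -0.082301927106299827, -0.071799821619154838, 0.42848347637737, 0.79377722262608719, 0.40517690240911824, -0.061123390002972552, -0.065771911281469364, 0.023452696142077168, 0.0077825964256727463, -0.0037935128643808019),
    dec_hi = c(0.0037935128643808019, 0.0077825964256727463, -0.023452696142077168, -0.065771911281469364, 0.061123390002972552, 0.40517690240911824, -0.79377722262608719, 0.42848347637737, 0.071799821619154838, -0.082301927106299827, -0.034555027573297738, 0.015880544863669452, 0.0090079761367306242, -0.0025745176881367972, -0.0011175187708306303, 0.00046621695982040288, 7.0983302506379004e-05, -3.4599773197272781e-05),
    rec_lo = c(-0.0037935128643808019, 0.0077825964256727463, 0.023452696142077168, -0.065771911281469364, -0.061123390002972552, 0.40517690240911824, 0.79377722262608719, 0.42848347637737, -0.071799821619154838, -0.082301927106299827, 0.034555027573297738, 0.015880544863669452, -0.0090079761367306242, -0.0025745176881367972, 0.0011175187708306303, 0.00046621695982040288, -7.0983302506379004e-05, -3.4599773197272781e-05),
    rec_hi = c(-3.4599773197272781e-05, 7.0983302506379004e-05, 0.00046621695982040288, -0.0011175187708306303, -0.0025745176881367972, 0.0090079761367306242, 0.015880544863669452, -0.034555027573297738, -0.082301927106299827, 0.071799821619154838, 0.42848347637737, -0.79377722262608719, 0.40517690240911824, 0.061123390002972552, -0.065771911281469364, -0.023452696142077168, 0.0077825964256727463, 0.0037935128643808019),
    orthogonal = TRUE
  ),
  "coif4" = list(
    dec_lo = c(-1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05, 6.2338854312787192e-05, -0.00025997433712225682, -0.00058902022463321654, 0.0012665610789256603, 0.0037514346971460866, -0.0056582838001308835, -0.015211728187697211, 0.025082253337949612, 0.039334422605589149, -0.096220424535952642, -0.066627472366817167, 0.43438603311435653, 0.78223893442428261, 0.41530842700068227, -0.056077319603569258, -0.081266710249193727, 0.02668230466960483, 0.016068947131575029, -0.0073461679362680507, -0.001629492425226786, 0.00089231390253700297),
    dec_hi = c(-0.00089231390253700297, -0.001629492425226786, 0.0073461679362680507, 0.016068947131575029, -0.02668230466960483, -0.081266710249193727, 0.056077319603569258, 0.41530842700068227, -0.78223893442428261, 0.43438603311435653, 0.066627472366817167, -0.096220424535952642, -0.039334422605589149, 0.025082253337949612, 0.015211728187697211, -0.0056582838001308835, -0.0037514346971460866, 0.0012665610789256603, 0.00058902022463321654, -0.00025997433712225682, -6.2338854312787192e-05, 3.1229861599195265e-05, 3.259647940030751e-06, -1.7849909144933469e-06),
    rec_lo = c(0.00089231390253700297, -0.001629492425226786, -0.0073461679362680507, 0.016068947131575029, 0.02668230466960483, -0.081266710249193727, -0.056077319603569258, 0.41530842700068227, 0.78223893442428261, 0.43438603311435653, -0.066627472366817167, -0.096220424535952642, 0.039334422605589149, 0.025082253337949612, -0.015211728187697211, -0.0056582838001308835, 0.0037514346971460866, 0.0012665610789256603, -0.00058902022463321654, -0.00025997433712225682, 6.2338854312787192e-05, 3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
    rec_hi = c(-1.7849909144933469e-06, 3.259647940030751e-06, 3.1229861599195265e-05, -6.2338854312787192e-05, -0.00025997433712225682, 0.00058902022463321654, 0.0012665610789256603, -0.0037514346971460866, -0.0056582838001308835, 0.015211728187697211, 0.025082253337949612, -0.039334422605589149, -0.096220424535952642, 0.066627472366817167, 0.43438603311435653, -0.78223893442428261, 0.41530842700068227, 0.056077319603569258, -0.081266710249193727, -0.02668230466960483, 0.016068947131575029, 0.0073461679362680507, -0.001629492425226786, -0.00089231390253700297),
    orthogonal = TRUE
  ),
  "coif5" = list(
    dec_lo = c(-9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06, -2.1270221672515614e-05, -4.1219861924265501e-05, 0.00014035632812373243, 0.00030185794166824478, -0.00063755892612588115, -0.0016616273039298788, 0.0024315754425382886, 0.0067615202206204169, -0.0091595073386761625, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834, -0.10556315130733723, -0.06203775157498196, 0.43798230665916338, 0.77429362286032744, 0.42157126673075435, -0.052046670253554764, -0.091921588060086087, 0.028169744270532353, 0.023408322118927783, -0.010131584846900276, -0.0041593126275786402, 0.0021782943778456947, 0.00035857774116175768, -0.000212081862067494),
    dec_hi = c(0.000212081862067494, 0.00035857774116175768, -0.0021782943778456947, -0.0041593126275786402, 0.010131584846900276, 0.023408322118927783, -0.028169744270532353, -0.091921588060086087, 0.052046670253554764, 0.42157126673075435, -0.77429362286032744, 0.43798230665916338, 0.06203775157498196, -0.10556315130733723, -0.041287530472117834, 0.032674799467057355, 0.019758391600965465, -0.0091595073386761625, -0.0067615202206204169, 0.0024315754425382886, 0.0016616273039298788, -0.00063755892612588115, -0.00030185794166824478, 0.00014035632812373243, 4.1219861924265501e-05, -2.1270221672515614e-05, -3.7007277113394796e-06, 2.0612203985788783e-06, 1.6237995172048338e-07, -9.6040101127678941e-08),
    rec_lo = c(-0.000212081862067494, 0.00035857774116175768, 0.0021782943778456947, -0.0041593126275786402, -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.091921588060086087, -0.052046670253554764, 0.42157126673075435, 0.77429362286032744, 0.43798230665916338, -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355, -0.019758391600965465, -0.0091595073386761625, 0.0067615202206204169, 0.0024315754425382886, -0.0016616273039298788, -0.00063755892612588115, 0.00030185794166824478, 0.00014035632812373243, -4.1219861924265501e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06, -1.6237995172048338e-07, -9.6040101127678941e-08),
    rec_hi = c(-9.6040101127678941e-08, 1.6237995172048338e-07, 2.0612203985788783e-06, -3.7007277113394796e-06, -2.1270221672515614e-05, 4.1219861924265501e-05, 0.00014035632812373243, -0.00030185794166824478, -0.00063755892612588115, 0.0016616273039298788, 0.0024315754425382886, -0.0067615202206204169, -0.0091595073386761625, 0.019758391600965465, 0.032674799467057355, -0.041287530472117834, -0.10556315130733723, 0.06203775157498196, 0.43798230665916338, -0.77429362286032744, 0.42157126673075435, 0.052046670253554764, -0.091921588060086087, -0.028169744270532353, 0.023408322118927783, 0.010131584846900276, -0.0041593126275786402, -0.0021782943778456947, 0.00035857774116175768, 0.000212081862067494),
    orthogonal = TRUE
  ),
  "bior1.1" = list(
    dec_lo = c(0.70710678118654757, 0.70710678118654757),
    dec_hi = c(-0.70710678118654757, 0.70710678118654757),
    rec_lo = c(0.70710678118654757, 0.70710678118654757),
    rec_hi = c(0.70710678118654757, -0.70710678118654757),
    orthogonal = FALSE
  ),
  "bior2.2" = list(
    dec_lo = c(0, -0.17677669529663689, 0.35355339059327379, 1.0606601717798212, 0.35355339059327379, -0.17677669529663689),
    dec_hi = c(-0, 0.35355339059327379, -0.70710678118654757, 0.35355339059327379, -0, 0),
    rec_lo = c(0, 0.35355339059327379, 0.70710678118654757, 0.35355339059327379, 0, 0),
    rec_hi = c(0, 0.17677669529663689, 0.35355339059327379, -1.0606601717798212, 0.35355339059327379, 0.17677669529663689),
    orthogonal = FALSE
  ),
  "bior3.3" = list(
    dec_lo = c(0.066291260736238825, -0.19887378220871649, -0.15467960838455727, 0.99436891104358249, 0.99436891104358249, -0.15467960838455727, -0.19887378220871649, 0.066291260736238825),
    dec_hi = c(-0, 0, -0.17677669529663689, 0.5303300858899106, -0.5303300858899106, 0.17677669529663689, -0, 0),
    rec_lo = c(0, 0, 0.17677669529663689, 0.5303300858899106, 0.5303300858899106, 0.17677669529663689, 0, 0),
    rec_hi = c(0.066291260736238825, 0.19887378220871649, -0.15467960838455727, -0.99436891104358249, 0.99436891104358249, 0.15467960838455727, -0.19887378220871649, -0.066291260736238825),
    orthogonal = FALSE
  ),
  "bior4.4" = list(
    dec_lo = c(0, 0.03782845550726404, -0.023849465019556843, -0.11062440441843718, 0.37740285561283066, 0.85269867900889385, 0.37740285561283066, -0.11062440441843718, -0.023849465019556843, 0.03782845550726404),
    dec_hi = c(-0, -0.064538882628697058, 0.040689417609164058, 0.41809227322161724, -0.7884856164055829, 0.41809227322161724, 0.040689417609164058, -0.064538882628697058, -0, 0),
    rec_lo = c(0, -0.064538882628697058, -0.040689417609164058, 0.41809227322161724, 0.7884856164055829, 0.41809227322161724, -0.040689417609164058, -0.064538882628697058, 0, 0),
    rec_hi = c(0, -0.03782845550726404, -0.023849465019556843, 0.11062440441843718, 0.37740285561283066, -0.85269867900889385, 0.37740285561283066, 0.11062440441843718, -0.023849465019556843, -0.03782845550726404),
    orthogonal = FALSE
  ),
  "bior5.5" = list(
    dec_lo = c(0, 0, 0.03968708834740544, 0.0079481086372403219, -0.054463788468236907, 0.34560528195603346, 0.73666018142821055, 0.34560528195603346, -0.054463788468236907, 0.0079481086372403219, 0.03968708834740544, 0),
    dec_hi = c(-0.013456709459118716, -0.0026949668801115071, 0.13670658466432914, -0.093504697400938863, -0.47680326579848425, 0.89950610974864842, -0.47680326579848425, -0.093504697400938863, 0.13670658466432914, -0.0026949668801115071, -0.013456709459118716, 0),
    rec_lo = c(0.013456709459118716, -0.0026949668801115071, -0.13670658466432914, -0.093504697400938863, 0.47680326579848425, 0.89950610974864842, 0.47680326579848425, -0.093504697400938863, -0.13670658466432914, -0.0026949668801115071, 0.013456709459118716, 0),
    rec_hi = c(0, -0, 0.03968708834740544, -0.0079481086372403219, -0.054463788468236907, -0.34560528195603346, 0.73666018142821055, -0.34560528195603346, -0.054463788468236907, -0.0079481086372403219, 0.03968708834740544, -0),
    orthogonal = FALSE
  ),
  "bior6.8" = list(
    dec_lo = c(0, 0.0019088317364812906, -0.0019142861290887667, -0.016990639867602342, 0.01193456527972926, 0.04973290349094079, -0.077263173167204144, -0.09405920349573646, 0.42079628460982682, 0.82592299745840225, 0.42079628460982682, -0.09405920349573646, -0.077263173167204144, 0.04973290349094079, 0.01193456527972926, -0.016990639867602342, -0.0019142861290887667, 0.0019088317364812906),
    dec_hi = c(-0, 0, -0, 0.014426282505624435, -0.014467504896790148, -0.078722001062628819, 0.040367979030339923, 0.41784910915027457, -0.75890772945365415, 0.41784910915027457, 0.040367979030339923, -0.078722001062628819, -0.014467504896790148, 0.014426282505624435, -0, 0, -0, 0),
    rec_lo = c(0, 0, 0, 0.014426282505624435, 0.014467504896790148, -0.078722001062628819, -0.040367979030339923, 0.41784910915027457, 0.75890772945365415, 0.41784910915027457, -0.040367979030339923, -0.078722001062628819, 0.014467504896790148, 0.014426282505624435, 0, 0, 0, 0),
    rec_hi = c(0, -0.0019088317364812906, -0.0019142861290887667, 0.016990639867602342, 0.01193456527972926, -0.04973290349094079, -0.077263173167204144, 0.09405920349573646, 0.42079628460982682, -0.82592299745840225, 0.42079628460982682, 0.09405920349573646, -0.077263173167204144, -0.04973290349094079, 0.01193456527972926, 0.016990639867602342, -0.0019142861290887667, -0.0019088317364812906),
    orthogonal = FALSE
  )
)

#' List the supported mother wavelets
#'
#' Returns the names of the wavelet filters available for
#' [wavelet_decompose()]: Daubechies (db2--db6), symlets (sym2--sym6),
#' coiflets (coif1--coif5) and spline biorthogonal wavelets (bior1.1,
#' bior2.2, bior3.3, bior4.4, bior5.5, bior6.8) -- 21 candidates in all.
#'
#' @return Character vector of wavelet names.
#' @export
list_wavelets <- function() names(.wavelet_registry)

wavelet_filters <- function(wavelet) {
  if (!is.character(wavelet) || length(wavelet) != 1L || !wavelet %in% names(.wavelet_registry)) {
    stop("unknown wavelet '", wavelet, "'; supported: ",
         paste(names(.wavelet_registry), collapse = ", "), call. = FALSE)
  }
  .wavelet_registry[[wavelet]]
}
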