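kind: photocycle_scenario
tau_s:
- 0.0002
- 0.016
- 0.065
sads:
- positive:
    lambda_max_nm: 600.0
    width_nm: 30.0
    amplitude: 0.8
  bleach:
    lambda_max_nm: 560.0
    width_nm: 30.0
    amplitude: 1.0
- positive:
    lambda_max_nm: 470.0
    width_nm: 30.0
    amplitude: 0.9
  bleach:
    lambda_max_nm: 560.0
    width_nm: 30.0
    amplitude: 1.0
- positive:
    lambda_max_nm: 620.0
    width_nm: 30.0
    amplitude: 0.55
  bleach:
    lambda_max_nm: 560.0
    width_nm: 30.0
    amplitude: 1.0
labels:
- K
- L
- O
wavelengths_nm:
- 420.0
- 430.0
- 440.0
- 450.0
- 460.0
- 470.0
- 480.0
- 490.0
- 500.0
- 510.0
- 520.0
- 530.0
- 540.0
- 550.0
- 560.0
- 570.0
- 580.0
- 590.0
- 600.0
- 610.0
- 620.0
- 630.0
- 640.0
- 650.0
- 660.0
- 670.0
- 680.0
- 690.0
- 700.0
- 710.0
times_s:
- 9.999999999999997e-06
- 1.244371825197359e-05
- 1.548461239345004e-05
- 1.926861538651107e-05
- 2.397732209753869e-05
- 2.983670406185919e-05
- 3.712795389132918e-05
- 4.62009797495966e-05
- 5.749119749691174e-05
- 7.15404263620139e-05
- 8.902289092749633e-05
- 1.10777577267794e-04
- 1.378484960156663e-04
- 1.715347845877256e-04
- 2.134530529822639e-04
- 2.656149651334878e-04
- 3.305237789628911e-04
- 4.112944780991813e-04
- 5.11803260405873e-04
- 6.368735572932148e-04
- 7.925075109088925e-04
- 9.861740178323144e-04
- 1.227167162532209e-03
- 1.527052241862468e-03
- 1.900220785378118e-03
- 2.364581206978928e-03
- 2.94241823235574e-03
- 3.661462346290495e-03
- 4.556220582744908e-03
- 5.669632522552056e-03
- 7.055130970286403e-03
- 8.779206202501697e-03
- 1.092459684599101e-02
- 1.359426051679115e-02
- 1.691631477148778e-02
- 2.105018548780927e-02
- 2.619425773620819e-02
- 3.259539630889542e-02
- 4.056079279793139e-02
- 5.047270776541377e-02
- 6.280681548470085e-02
- 7.815503161953095e-02
- 9.725391934475304e-02
- 1.210200371226269e-01
- 1.505939244797353e-01
- 1.873948366684815e-01
- 2.331888549377189e-01
- 2.901736410345315e-01
- 3.610839033183032e-01
- 4.493226358215837e-01
- 5.591244284397923e-01
- 6.957586855300533e-01
- 8.657825054099477e-01
- 1.077355356480919e+00
- 1.34063065133031e+00
- 1.668243010511422e+00
- 2.075914599862835e+00
- 2.583209639585162e+00
- 3.214473294078e+00
- 4.0e+00
noise_sigma: 0.01
seed: 1
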