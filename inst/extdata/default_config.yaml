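n_patients: 221
seed: 1
spearman_targets:
  cd3_ct:
    cd3_ct: 1.0
    cd3_im: 0.2
    cd8_ct: 0.2
    cd8_im: 0.2
    cd20_ct: 0.2
    cd20_im: 0.2
    cd138_ct: 0.246
    cd138_im: 0.2
  cd3_im:
    cd3_ct: 0.2
    cd3_im: 1.0
    cd8_ct: 0.2
    cd8_im: 0.606
    cd20_ct: 0.2
    cd20_im: 0.442
    cd138_ct: 0.2
    cd138_im: 0.2
  cd8_ct:
    cd3_ct: 0.2
    cd3_im: 0.2
    cd8_ct: 1.0
    cd8_im: 0.2
    cd20_ct: 0.2
    cd20_im: 0.2
    cd138_ct: 0.2
    cd138_im: 0.2
  cd8_im:
    cd3_ct: 0.2
    cd3_im: 0.606
    cd8_ct: 0.2
    cd8_im: 1.0
    cd20_ct: 0.2
    cd20_im: 0.459
    cd138_ct: 0.2
    cd138_im: 0.2
  cd20_ct:
    cd3_ct: 0.2
    cd3_im: 0.2
    cd8_ct: 0.2
    cd8_im: 0.2
    cd20_ct: 1.0
    cd20_im: 0.2
    cd138_ct: 0.421
    cd138_im: 0.2
  cd20_im:
    cd3_ct: 0.2
    cd3_im: 0.442
    cd8_ct: 0.2
    cd8_im: 0.459
    cd20_ct: 0.2
    cd20_im: 1.0
    cd138_ct: 0.2
    cd138_im: 0.2
  cd138_ct:
    cd3_ct: 0.246
    cd3_im: 0.2
    cd8_ct: 0.2
    cd8_im: 0.2
    cd20_ct: 0.421
    cd20_im: 0.2
    cd138_ct: 1.0
    cd138_im: 0.2
  cd138_im:
    cd3_ct: 0.2
    cd3_im: 0.2
    cd8_ct: 0.2
    cd8_im: 0.2
    cd20_ct: 0.2
    cd20_im: 0.2
    cd138_ct: 0.2
    cd138_im: 1.0
density_marginals:
- variable: cd3_ct
  meanlog: 5.703782474656201
  sdlog: 0.9
- variable: cd3_im
  meanlog: 6.214608098422191
  sdlog: 0.9
- variable: cd8_ct
  meanlog: 4.605170185988092
  sdlog: 0.9
- variable: cd8_im
  meanlog: 5.298317366548036
  sdlog: 0.9
- variable: cd20_ct
  meanlog: 3.688879454113936
  sdlog: 0.9
- variable: cd20_im
  meanlog: 4.382026634673881
  sdlog: 0.9
- variable: cd138_ct
  meanlog: 5.010635294096256
  sdlog: 0.9
- variable: cd138_im
  meanlog: 4.787491742782046
  sdlog: 0.9
covariate_marginals:
  sex:
    female: 0.497737556561086
    male: 0.502262443438914
  age_group:
    <65: 0.307692307692308
    65-75: 0.321266968325792
    '>75': 0.3710407239819
  location:
    proximal: 0.420814479638009
    distal: 0.271493212669683
    rectum: 0.307692307692308
  stage:
    I: 0.204545454545455
    II: 0.336363636363636
    III: 0.304545454545455
    IV: 0.154545454545455
  grade:
    low: 0.886363636363636
    high: 0.113636363636364
  lvi:
    'no': 0.502283105022831
    'yes': 0.497716894977169
  mmr:
    proficient: 0.868181818181818
    deficient: 0.131818181818182
  braf:
    wildtype: 0.904977375565611
    mutant: 0.095022624434389
covariate_missing:
  stage: 1
  grade: 1
  mmr: 1
  lvi: 2
stage_by_tscore:
  low:
    I: 0.148648648648649
    II: 0.22972972972973
    III: 0.297297297297297
    IV: 0.324324324324324
  intermediate:
    I: 0.189189189189189
    II: 0.418918918918919
    III: 0.324324324324324
    IV: 0.067567567567568
  high:
    I: 0.277777777777778
    II: 0.361111111111111
    III: 0.291666666666667
    IV: 0.069444444444444
hazard_spec:
  cancer:
    base_rate: 0.0061
    loghr:
      tscore:
        intermediate: -0.63487827243597
        high: -1.514127732629776
  other:
    base_rate: 0.00355
    loghr:
      tscore:
        intermediate: -0.864487004399459
        high: -0.200858506524775
admin_censor_months: 120.0
accrual_span_months: 80.0
lock_offset_months: 80.0
surgical_mortality_count: 2
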