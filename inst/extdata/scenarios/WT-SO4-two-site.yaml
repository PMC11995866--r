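kind: titration_scenario
model_kind: two_site
Kd1_mM: 1.2
Kd2_mM: 82.0
Vmax1: 0.6
shift_direction: red
unbound_band:
  lambda_max_nm: 545.0
  width_nm: 35.0
  amplitude: 1.0
bound_band:
  lambda_max_nm: 560.0
  width_nm: 35.0
  amplitude: 1.0
concentrations_mM:
- 0.0
- 0.001
- 0.002069138081115
- 0.004281332398719
- 0.008858667904101
- 0.018329807108324
- 0.037926901907323
- 0.078475997035146
- 0.162377673918872
- 0.335981828628378
- 0.695192796177561
- 1.438449888287663
- 2.976351441631318
- 6.158482110660263
- 12.742749857031336
- 26.366508987303579
- 54.555947811685186
- 112.883789168468894
- 233.57214690901219
- 483.293023857175228
- 999.999999999999773
wavelengths_nm:
- 400.0
- 402.0
- 404.0
- 406.0
- 408.0
- 410.0
- 412.0
- 414.0
- 416.0
- 418.0
- 420.0
- 422.0
- 424.0
- 426.0
- 428.0
- 430.0
- 432.0
- 434.0
- 436.0
- 438.0
- 440.0
- 442.0
- 444.0
- 446.0
- 448.0
- 450.0
- 452.0
- 454.0
- 456.0
- 458.0
- 460.0
- 462.0
- 464.0
- 466.0
- 468.0
- 470.0
- 472.0
- 474.0
- 476.0
- 478.0
- 480.0
- 482.0
- 484.0
- 486.0
- 488.0
- 490.0
- 492.0
- 494.0
- 496.0
- 498.0
- 500.0
- 502.0
- 504.0
- 506.0
- 508.0
- 510.0
- 512.0
- 514.0
- 516.0
- 518.0
- 520.0
- 522.0
- 524.0
- 526.0
- 528.0
- 530.0
- 532.0
- 534.0
- 536.0
- 538.0
- 540.0
- 542.0
- 544.0
- 546.0
- 548.0
- 550.0
- 552.0
- 554.0
- 556.0
- 558.0
- 560.0
- 562.0
- 564.0
- 566.0
- 568.0
- 570.0
- 572.0
- 574.0
- 576.0
- 578.0
- 580.0
- 582.0
- 584.0
- 586.0
- 588.0
- 590.0
- 592.0
- 594.0
- 596.0
- 598.0
- 600.0
- 602.0
- 604.0
- 606.0
- 608.0
- 610.0
- 612.0
- 614.0
- 616.0
- 618.0
- 620.0
- 622.0
- 624.0
- 626.0
- 628.0
- 630.0
- 632.0
- 634.0
- 636.0
- 638.0
- 640.0
- 642.0
- 644.0
- 646.0
- 648.0
- 650.0
- 652.0
- 654.0
- 656.0
- 658.0
- 660.0
- 662.0
- 664.0
- 666.0
- 668.0
- 670.0
- 672.0
- 674.0
- 676.0
- 678.0
- 680.0
- 682.0
- 684.0
- 686.0
- 688.0
- 690.0
- 692.0
- 694.0
- 696.0
- 698.0
- 700.0
noise_sigma: 0.01
seed: 1
anion: SO4
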