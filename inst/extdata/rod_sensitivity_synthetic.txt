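# synthetic rod spectral sensitivity (log-normal shape, 500 nm peak),
# expressed as probability of isomerization per photon
# columns: wavelength_nm sensitivity
380 0.00278355
390 0.00804347
400 0.0204437
410 0.0461075
420 0.093021
430 0.169119
440 0.278965
450 0.420104
460 0.580908
470 0.74148
480 0.877928
490 0.968616
500 1
510 0.969828
520 0.886764
530 0.76701
540 0.62956
550 0.491797
560 0.366634
570 0.26151
580 0.178891
590 0.117627
600 0.0744994
610 0.0455387
620 0.026915
630 0.0154081
640 0.00855765
650 0.00461827
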