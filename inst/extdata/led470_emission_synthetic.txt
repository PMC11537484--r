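# synthetic LED emission spectrum (Gaussian, 470 nm peak, 18 nm SD)
# columns: wavelength_nm relative_power
380 3.72665e-06
385 1.43797e-05
390 5.13655e-05
395 0.000169857
400 0.000519976
405 0.00147358
410 0.00386592
415 0.00938906
420 0.0211097
425 0.0439369
430 0.084658
435 0.151007
440 0.249352
445 0.381171
450 0.539408
455 0.706648
460 0.856997
465 0.962154
470 1
475 0.962154
480 0.856997
485 0.706648
490 0.539408
495 0.381171
500 0.249352
505 0.151007
510 0.084658
515 0.0439369
520 0.0211097
525 0.00938906
530 0.00386592
535 0.00147358
540 0.000519976
545 0.000169857
550 5.13655e-05
555 1.43797e-05
560 3.72665e-06
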