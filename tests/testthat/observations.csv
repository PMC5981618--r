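frame_path,pupil_x,pupil_y,quality,blink
frame_000001.png,140.48806744051737,86.83778429168699,1,0
frame_000002.png,139.27355385054148,86.69793074559162,1,0
frame_000003.png,310.0558803568464,95.62231355879126,0.8641975308641975,0
frame_000004.png,311.20029382034437,96.58427397466193,1,0
frame_000005.png,489.34906015748675,104.56173036694186,1,0
frame_000006.png,491.1807367489274,103.86971021992183,1,0
frame_000007.png,148.44730598934476,214.23505962066093,1,0
frame_000008.png,149.5472927237698,215.47586701931505,0.6666666666666666,0
frame_000009.png,320.11739318305115,220.50715495862462,1,0
frame_000010.png,319.746230530039,222.89793336430367,1,0
frame_000011.png,502.7895622011215,235.2701409068929,0.6319018404907976,0
frame_000012.png,499.63957052196264,232.22472664563182,1,0
frame_000013.png,157.323222723221,344.1172242028083,1,0
frame_000014.png,157.9098079711624,343.46781396333813,1,0
frame_000015.png,330.76096781246724,352.6021719984214,0.9447852760736196,0
frame_000016.png,328.26275804133996,352.9060328817806,0.9329268292682927,0
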