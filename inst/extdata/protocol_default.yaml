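sequences:
- name: FLAIR
  kind: anatomical
  tr_ms: 8000.0
  te_ms:
  - 81.0
  ti_ms:
  - 2370.0
  flip_deg:
  - 90.0
  refocus_deg: 150.0
  duration: '01:54'
  voxel_mm:
  - 0.7
  - 0.7
  - 4.0
  comments: 2D turbo inversion recovery; turbo factor 16; strong fat saturation
- name: MP2RAGE
  kind: anatomical
  tr_ms: 4000.0
  te_ms:
  - 3.52
  ti_ms:
  - 716.0
  - 2180.0
  flip_deg:
  - 5.0
  duration: '06:00'
  voxel_mm:
  - 1.0
  - 1.0
  - 1.0
  comments: 3D turbo-flash, two inversion contrasts; GRAPPA 2 (26 ref. lines)
- name: MESE
  kind: mese
  tr_ms: 5000.0
  te_ms:
  - 12.0
  - 24.0
  - 36.0
  - 48.0
  - 60.0
  - 72.0
  - 84.0
  - 96.0
  - 108.0
  - 120.0
  - 132.0
  - 144.0
  flip_deg:
  - 90.0
  refocus_deg: 160.0
  duration: '07:35'
  voxel_mm:
  - 1.0
  - 1.0
  - 3.0
  comments: 2D multi-echo spin-echo, 12 echoes at 12 ms spacing
- name: MEGRE
  kind: megre
  tr_ms: 41.0
  te_ms:
  - 5.2
  - 9.72857142857
  - 14.2571428571
  - 18.7857142857
  - 23.3142857143
  - 27.8428571429
  - 32.3714285714
  - 36.9
  flip_deg:
  - 15.0
  duration: '05:50'
  voxel_mm:
  - 1.0
  - 1.0
  - 1.0
  comments: 3D multi-echo gradient-echo, monopolar readout; magnitude + phase
- name: IR-EPI
  kind: irepi
  tr_ms: 3270.0
  te_ms:
  - 49.0
  ti_ms:
  - 200.0
  - 400.0
  - 1200.0
  - 2400.0
  flip_deg:
  - 90.0
  refocus_deg: 180.0
  duration: '04:20'
  voxel_mm:
  - 2.0
  - 2.0
  - 3.0
  comments: 2D inversion-recovery spin-echo EPI at four inversion times
- name: VFA-SPGR
  kind: vfa
  tr_ms: 26.0
  te_ms:
  - 3.23
  flip_deg:
  - 5.0
  - 12.0
  - 27.0
  duration: '06:36'
  voxel_mm:
  - 1.0
  - 1.0
  - 2.2
  comments: 3D spoiled gradient-echo at three flip angles
- name: DWI
  kind: dwi
  tr_ms: 3500.0
  te_ms:
  - 62.8
  flip_deg:
  - 90.0
  refocus_deg: 160.0
  bvalues_s_mm2:
  - 0.0
  - 1000.0
  n_directions: 64
  duration: '03:58'
  voxel_mm:
  - 2.0
  - 2.0
  - 2.0
  comments: 2D multiband EPI, phase encoding A>>P
- name: DWI-revPE
  kind: dwi
  tr_ms: 3500.0
  te_ms:
  - 62.8
  flip_deg:
  - 90.0
  refocus_deg: 160.0
  bvalues_s_mm2:
  - 0.0
  - 1000.0
  n_directions: 6
  duration: '00:35'
  voxel_mm:
  - 2.0
  - 2.0
  - 2.0
  comments: reversed phase-encode (P>>A) segment, six directions
- name: ihMT
  kind: ihmt
  tr_ms: 345.0
  te_ms:
  - 2.62
  flip_deg:
  - 4.0
  duration: '08:42'
  voxel_mm:
  - 2.0
  - 2.0
  - 2.0
  comments: 3D GRE with bursts of Tukey-windowed MT preparation pulses at
    +/- 7 kHz; five saturation conditions
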