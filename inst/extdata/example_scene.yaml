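# Example synthetic-scene specification for `sedisloc simulate` /
# cliSimulate(): a 64 x 64 scan of a bent thin crystal crossed by a
# mixed dislocation with a right-handed screw component.
scan_shape: [64, 64]
scan_step: 8          # nm per scan pixel
det_shape: [64, 64]
detector_cal: 0.012   # 1/Angstrom per detector pixel
kV: 300
alpha: 0.8            # mrad
current: 1            # pA
dwell: 1              # ms
phase_C: 75           # planted Burgers azimuth, degrees
amp_A: 24             # nm
shape_B: 2
handedness: 1
seed: 42
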