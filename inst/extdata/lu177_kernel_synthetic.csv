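# Synthetic radial dose-point-kernel profile for Lu-177 electrons in water.
# Columns: radius_mm, dose_weight (relative energy deposition density per
# unit volume at that radius; interpolated linearly and renormalized to unit
# total energy when voxelized). This is a constructed stand-in with the
# qualitative shape of a short-range beta kernel (mean beta energy 147.9 keV,
# practical range < ~2 mm), NOT a Monte Carlo tabulation; the dose engine is
# a documented surrogate for full radiation transport.
radius_mm,dose_weight
0.0,1.0
0.25,0.55
0.5,0.28
0.75,0.13
1.0,0.055
1.25,0.022
1.5,0.008
1.75,0.002
2.0,0.0
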