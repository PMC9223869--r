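# Raw atomic properties behind the carbon-scaled weighting schemes.
# mass: IUPAC standard atomic weights (2021), u
# vdw_radius: Bondi (1964) van der Waals radii, angstrom (B: Batsanov 2001);
#   the volume scheme uses (4/3) pi r^3 of these radii
# electronegativity: Sanderson scale (as used by the Dragon descriptor system)
# polarizability: static dipole polarizability, 10^-24 cm^3, CRC Handbook
# ionization: first ionization energy, eV, CRC Handbook
element,mass,vdw_radius,electronegativity,polarizability,ionization
H,1.008,1.20,2.592,0.667,13.598
B,10.811,1.80,2.275,3.030,8.298
C,12.011,1.70,2.746,1.760,11.260
N,14.007,1.55,3.194,1.100,14.534
O,15.999,1.52,3.654,0.802,13.618
F,18.998,1.47,4.000,0.557,17.423
Si,28.086,2.10,2.138,5.380,8.152
P,30.974,1.80,2.515,3.630,10.487
S,32.060,1.80,2.957,2.900,10.360
Cl,35.453,1.75,3.475,2.180,12.968
Br,79.904,1.85,3.219,3.050,11.814
I,126.904,1.98,2.778,5.350,10.451
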