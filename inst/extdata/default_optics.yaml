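# Default tissue optics for the semi-infinite diffuse speckle model
mu_a: 0.1          # absorption, 1/cm
mu_s_prime: 10     # reduced scattering, 1/cm
wavelength: 7.85e-5  # vacuum wavelength, cm (785 nm)
n_tissue: 1.4
n_medium: 1.0
rho: 3             # source-detector separation, cm
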