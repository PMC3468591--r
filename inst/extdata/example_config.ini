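# Example run configuration for the echogam pipeline.
# Values mirror scene_config() / true_response() argument names; unknown
# keys are rejected. bathymetry_knots pairs are "distance:depth" separated
# by semicolons.

[scene]
transect_length = 1000
max_depth = 100
bathymetry_knots = 0:15; 200:70; 500:100; 800:70; 1000:15
n_days = 2
dawn_hour = 7
dusk_hour = 19
seed = 1

[truth]
intercept = -0.8

[models]
families = quasipoisson, negbinomial, binomial, gaussian_presence
k = 3
alpha = 0.05

[diagnostics]
n_perm = 199
seed = 1
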