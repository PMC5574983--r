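# Reference parameter set: the tristable regime of the circuit
# (a1 = 0.8, a2 = 0.85 with the default constants).
ref_params <- function() model_params(a1 = 0.8, a2 = 0.85)

# Independently computed reference values, frozen from a bisection oracle
# (stats::uniroot on the drift components, tol 1e-12).
ref <- list(
  x1_low    = 0.2409110,
  x1_saddle = 0.3374261,
  x1_high   = 0.9409195,
  L  = c(0.2409110, 1.7937609),
  B  = c(0.9409195, 0.0742635),
  u1 = c(0.9409195, 0.5016495),
  S  = c(0.9409195, 0.8211075),
  U2 = c(0.3374261, 1.6714650),
  curv_B = 0.9777412, curv_S = 0.5599910, curv_u1 = -0.6943366,
  dU_u1B = 0.0342724, dU_u1S = 0.0112069,
  Dc_kramers = 0.0827724
)

stable_points <- function(fps) fps[fps$stability == "stable", ]
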