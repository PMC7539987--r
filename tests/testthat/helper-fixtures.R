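# Shared fixtures. Everything is generated in code; the kinetic models are
# cached inside the package after the first calibration root-find.

cv_model <- function() default_kinetic_model("c_vulgaris")
at_model <- function() default_kinetic_model("a_thaliana")

# a short in-vivo protocol to keep simulations cheap in unit tests:
# 2 min dark adaptation, 5 min light, 5 min dark
short_protocol <- function(irradiance = 2000, inhibitor = FALSE) {
  npq_protocol(irradiance = irradiance, light_s = 300, dark_s = 300,
               inhibitor = inhibitor)
}

default_77k_areas <- c(standard = 1, psii_686 = 2.0, psii_698 = 1.2,
                       psi_720 = 2.5, vibronic = 0.8)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

with_test_seed <- function(seed, expr) {
  withr::local_seed(seed)
  expr
}
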