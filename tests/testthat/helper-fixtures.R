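# shared fixtures: the standard 20-um device and the worked-example system

std_geom <- function() channel_geometry(h = 20)

std_cf <- function() cf_model_for_depth(20)

# circuit of the preliminary demonstration (printed compliances, mu_b
# completed by consistency with the printed decay rates)
demo_params <- function(mu_b = 2.2266) {
  circuit_parameters(std_geom(), fluid_pair(1, mu_b),
                     C1 = 53.3, C2 = 1398.2, CF0 = 1.183)
}

# random physical parameter draw used by roundtrip/property tests
draw_params <- function() {
  C1 <- exp(runif(1, log(10), log(200)))
  C2 <- exp(runif(1, log(500), log(5000)))
  mu_b <- runif(1, 1, 4)
  circuit_parameters(std_geom(), fluid_pair(1, mu_b), C1 = C1, C2 = C2,
                     CF0 = 1.183)
}
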