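# shared fixtures, all generated in code

biv <- cona_example(2)
tri <- cona_example(3)
biv_conc <- total_concentrations(biv$schedule)
tri_conc <- total_concentrations(tri$schedule)

# random micro-rate model and free-ligand concentration, reproducible
random_instance <- function(s = sample(1:3, 1)) {
  list(rates = micro_rates(10^runif(s, -2, 3), 10^runif(s, -2, 3)),
       L = 10^runif(1, -3, 1))
}

# independent K_a oracle: membership-weighted stationary macro occupancies
ka_occupancy_oracle <- function(Q) {
  chi <- pcca_memberships(Q)$chi
  pi <- stationary_distribution(Q)
  pic <- crossprod(chi, pi)
  pic[2] / (pic[1] * Q$L_free)
}
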