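# Shared model builders and a random-model generator for property tests.

bd_model <- function(ksyn = 10, kd = 0.2, n0 = 50) {
  ssa_model(
    list(ssa_species("mRNA", n0)),
    list(ssa_reaction("Rsyn", NULL, c(mRNA = 1), ksyn),
         ssa_reaction("Rdeg", c(mRNA = 1), NULL, kd)))
}

chain_model <- function(nA = 1) {
  ssa_model(
    list(ssa_species("A", nA), ssa_species("B", 0), ssa_species("C", 0)),
    list(ssa_reaction("R1", c(A = 1), c(B = 1), 1),
         ssa_reaction("R2", c(B = 1), c(C = 1), 1)))
}

# random valid mass-action network over 2-3 species; propensities stay
# bounded because every synthesis is paired with first-order decay
random_model <- function() {
  nsp <- sample(2:3, 1)
  sp <- lapply(seq_len(nsp), function(i)
    ssa_species(paste0("S", i), sample(0:20, 1)))
  sn <- paste0("S", seq_len(nsp))
  rx <- list()
  for (i in seq_len(nsp)) {
    rx[[length(rx) + 1L]] <- ssa_reaction(paste0("syn", i), NULL,
                                          setNames(1L, sn[i]),
                                          runif(1, 0.5, 5))
    rx[[length(rx) + 1L]] <- ssa_reaction(paste0("deg", i),
                                          setNames(1L, sn[i]), NULL,
                                          runif(1, 0.1, 1))
  }
  if (nsp >= 2 && runif(1) < 0.7)
    rx[[length(rx) + 1L]] <- ssa_reaction("conv", setNames(1L, sn[1]),
                                          setNames(1L, sn[2]),
                                          runif(1, 0.1, 1))
  if (runif(1) < 0.5)
    rx[[length(rx) + 1L]] <- ssa_reaction("dimer", setNames(2L, sn[1]),
                                          NULL, runif(1, 0.01, 0.1))
  ssa_model(sp, rx)
}

# hand-built exact trajectory for definition-level tests
toy_trajectory <- function(times, states, fired, reactions = c("R1", "R2"),
                           props = NULL, species = "X") {
  states <- matrix(states, ncol = length(species),
                   dimnames = list(NULL, species))
  if (is.null(props))
    props <- matrix(1, nrow = length(times), ncol = length(reactions),
                    dimnames = list(NULL, reactions))
  structure(list(times = times, states = states, propensities = props,
                 fired = fired, firings = NULL, absorbing = FALSE,
                 clipped = FALSE, exact = TRUE, terminal = FALSE,
                 end_mode = "steps", end_value = length(times) - 1L,
                 species = species, reactions = reactions, model = NULL),
            class = "ssa_trajectory")
}
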