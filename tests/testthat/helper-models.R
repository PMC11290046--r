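# Shared toy models and builders.

one_pop <- function(ne = 5000, n_chrom = 2L)
  demographic_model(list(ecodeme("A", 1, ne = ne)),
                    sampling = c(A = n_chrom))

two_pop <- function(T_split = 1000, m_max = 0, m_min = 0, ne = 5000,
                    lambda = 1)
  demographic_model(
    list(ecodeme("A", 1, ne = ne), ecodeme("B", 2, ne = ne),
         ecodeme("AB", 3, ne = ne)),
    list(soft_split("AB", "A", "B", T_split, m_max = m_max,
                    m_min = m_min, lambda_decay = lambda)))

three_pop <- function(t1 = 1000, t2 = 3000, ne = 5000, m_max = 0)
  gp4pg:::caterpillar_model(c("A", "B", "C"), c(t1, t2),
                            fixture_scale(ne = ne, m_max = m_max), "X")

# Eight-group analogue of the favoured human topology: the Amazigh
# group diverges early from the Eurasian branch, the North African Arab
# group splits from the Middle East late.
model_d8 <- function() {
  tips <- c("Arab", "MiddleEast", "Europe", "Amazigh", "EastAsia",
            "EastAfrica", "WestAfrica", "San")
  times <- c(55, 1000, 1400, 1800, 2400, 3000, 4000)
  gp4pg:::caterpillar_model(tips, times, fixture_scale(m_max = 0.005), "D")
}

random_counts <- function(n_sites, n_pops, seed = 1) {
  gp4pg:::with_seed(seed, {
    m <- matrix(sample(0:2, n_sites * n_pops, replace = TRUE),
                n_sites, n_pops,
                dimnames = list(NULL, paste0("p", seq_len(n_pops))))
    storage.mode(m) <- "integer"
    m
  })
}
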