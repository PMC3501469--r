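# Independent oracles and small fixture builders shared across tests.

# Exhaustive fate-enumeration CJS probability of one history: the fish
# survives segments 1..a and dies in segment a+1 (a = T means survived
# everything); detection outcomes are Bernoulli while alive and impossible
# afterwards. Independent of the package's chi-recursion implementation.
brute_force_history_prob <- function(y, phi, p) {
  T_occ <- length(y)
  total <- 0
  for (a in 0:T_occ) {
    surv <- if (a > 0) prod(phi[seq_len(a)]) else 1
    death <- if (a < T_occ) (1 - phi[a + 1]) else 1
    if (a < T_occ && any(y[(a + 1):T_occ] == 1)) next # detected while dead
    det <- 1
    if (a > 0) {
      det <- prod(ifelse(y[seq_len(a)] == 1, p[seq_len(a)],
                         1 - p[seq_len(a)]))
    }
    total <- total + surv * death * det
  }
  total
}

# encounter_histories from history strings like "10110" (release digit
# included), with a minimal matching fish table
make_eh <- function(strings, population = "SkokomishW", year = 2008L,
                    origin = NULL, smolt_index = 3L) {
  n <- length(strings)
  h <- t(vapply(strings, function(s) as.integer(strsplit(s, "")[[1]]),
                integer(nchar(strings[1]))))
  rec <- fish_records(data.frame(
    fish_id = sprintf("F%03d", seq_len(n)),
    population = rep_len(population, n), year = rep_len(year, n),
    fork_length_mm = 180, weight_g = 55,
    smolt_index = rep_len(smolt_index, n),
    release_date = 120L, release_site = "PR"))
  if (!is.null(origin)) rec$origin <- rep_len(origin, n)
  dimnames(h) <- NULL
  encounter_histories(h, rec,
                      occasion_names = OCCASION_LINES[seq_len(ncol(h) - 1)])
}

# small three-table fixture (fish / receivers / events) built in code
make_tiny_tables <- function() {
  fish <- fish_records(data.frame(
    fish_id = c("A1", "A2", "A3"),
    population = c("BigBeefW", "SkokomishW", "SkokomishH"),
    year = 2008L,
    fork_length_mm = c(183, 180, 171),
    weight_g = c(57.6, 53.7, 49.0),
    smolt_index = c(3L, 2L, 1L),
    release_date = c(110L, 125L, 122L),
    release_site = c("PR-BigBeefW", "PR-SkokomishW", "PR-SkokomishW")))
  fish$release_time <- as.numeric(fish$release_date)
  receivers <- default_receivers()
  events <- detection_events(data.frame(
    fish_id = c("A1", "A2", "A2"),
    receiver_id = c("RMBB-01", "RMSK-01", "HCB-03"),
    timestamp = c(111.5, 126.0, 131.2)), receivers)
  list(fish = fish, receivers = receivers, events = events)
}
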