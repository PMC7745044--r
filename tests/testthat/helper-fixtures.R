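# Small fixtures shared across test files.

# weighted triangle whose distance graph has direct A-C length 7 and a
# two-hop detour via B of total length 6 (weights from l = 1/x - 1)
fig1_triangle <- function() {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "C"] <- w["C", "A"] <- 1 / 8   # l = 7
  w["A", "B"] <- w["B", "A"] <- 1 / 3   # l = 2
  w["B", "C"] <- w["C", "B"] <- 1 / 5   # l = 4
  fc_matrix(w)
}

random_fc <- function(n, seed, lo = 0.05, hi = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  w[up] <- runif(sum(up), lo, hi)
  w <- w + t(w)
  fc_matrix(w)
}

short_paradigm <- function() {
  task_paradigm(default_paradigm_blocks(
    n_task_blocks = 2, task_duration = 20, initial_rest = 10,
    inter_rest = 10))
}

uniform_fc <- function(n, x) {
  w <- matrix(x, n, n)
  fc_matrix(w)
}

make_balanced_table <- function(seed, n_per_group = 6, effect = 0,
                                interaction = 0) {
  set.seed(seed)
  rows <- list()
  sid <- 0
  for (g in c("student", "nurse")) for (k in seq_len(n_per_group)) {
    sid <- sid + 1
    base <- rnorm(1)
    for (s in c("affective", "neutral")) {
      val <- base + rnorm(1, sd = 0.5) +
        (s == "affective") * effect +
        (g == "student" && s == "affective") * interaction
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("s%02d", sid), group = g, state = s,
        region = "global", index = "SMP", value = val)
    }
  }
  do.call(rbind, rows)
}
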