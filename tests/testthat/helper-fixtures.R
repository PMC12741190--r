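# Shared in-code fixtures for the test suite.

# A tiny feature table with explicit values.
tiny_table <- function(values = NULL, modality = "metabolite") {
  if (is.null(values)) {
    values <- matrix(c(2, 3, 5, 1, 2, 3), nrow = 3,
                     dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  }
  feature_table(values, modality = modality)
}

# Metadata for arbitrary sample ids: ages spread over the lifespan,
# groups assigned from the default boundaries, sexes alternating.
meta_for <- function(ids, ages = NULL) {
  n <- length(ids)
  if (is.null(ages)) ages <- seq(0, 84, length.out = n)
  data.frame(sample_id = ids, age = ages,
             sex = rep(c("F", "M"), length.out = n),
             group = assign_life_stage(ages), stringsAsFactors = FALSE)
}

# A small two-group table: n_a samples in group A (newborn) and n_b in G.
two_group_fixture <- function(n_feat = 10, n_a = 6, n_b = 6, delta = 0,
                              sigma = 0.2, seed = 42) {
  set.seed(seed)
  ids <- c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b)))
  shift <- c(rep(delta, n_a), rep(0, n_b))
  values <- t(vapply(seq_len(n_feat), function(i)
    exp(shift + rnorm(n_a + n_b, 0, sigma)), numeric(n_a + n_b)))
  dimnames(values) <- list(sprintf("f%03d", seq_len(n_feat)), ids)
  m <- data.frame(sample_id = ids,
                  age = c(rep(0, n_a), runif(n_b, 66, 80)),
                  sex = rep(c("F", "M"), length.out = n_a + n_b),
                  group = c(rep("A_newborn", n_a),
                            rep("G_late_adulthood", n_b)),
                  stringsAsFactors = FALSE)
  list(table = feature_table(values), meta = m)
}

# Naive O(m^2) BH step-up: q_i = min over j with p_j >= p_i of m * p_j / r_j
# where r_j is the rank of p_j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- integer(m); r[ord] <- seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m)) {
    suffix <- which(r >= r[i])
    q[i] <- min(1, min(m * p[suffix] / r[suffix]))
  }
  q
}

# Brute-force pairwise AUC (tie-corrected Mann-Whitney).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
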