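# Independent oracles used across tests.

# character-level edit distance by textbook dynamic programming
dp_edit_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + cost)
    }
  }
  D[n + 1, m + 1]
}

# exhaustive maximum-weight one-to-one assignment over a score matrix with
# NA marking inadmissible pairs; returns the optimal total score
brute_force_assignment <- function(score) {
  np <- nrow(score); nt <- ncol(score)
  rec <- function(i, used) {
    if (i > np) return(0)
    best <- rec(i + 1L, used)            # pred i left unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && !is.na(score[i, j])) {
        used[j] <- TRUE
        best <- max(best, score[i, j] + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nt))
}

# direct-formula concordance statistics (no stats::cor)
oracle_paired_stats <- function(a, b) {
  n <- length(a)
  pear <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  list(
    pearson = pear(a, b),
    spearman = pear(rank(a), rank(b)),
    mad = mean(abs(a - b)),
    rmsd = sqrt(mean((a - b)^2))
  )
}

# measurement tables with controlled keys for alignment tests
make_entries <- function(enzymes, substrates, kcat = NULL, km = NULL,
                         organisms = "escherichia coli", mutations = "") {
  n <- length(enzymes)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    kinetic_measurement(
      enzyme_name = enzymes[i],
      organism = rep_len(organisms, n)[i],
      mutation = rep_len(mutations, n)[i],
      substrate_name = rep_len(substrates, n)[i],
      kcat_canonical = if (is.null(kcat)) NA_real_ else kcat[i],
      km_canonical = if (is.null(km)) NA_real_ else km[i],
      doc_id = paste0("D", i), row_index = i - 1L
    )
  }))
}

# ground-truth tibble in the schema produced by read_ground_truth()
make_truth <- function(enzymes, substrates, values, parameter = "kcat",
                       organisms = "escherichia coli", mutations = "") {
  n <- length(enzymes)
  tibble::tibble(
    enzyme_name = enzymes,
    mutation = rep_len(mutations, n),
    substrate_name = substrates,
    organism = rep_len(organisms, n),
    substrate_smiles = "",
    value = as.character(values),
    unit = if (parameter == "kcat") "s^-1" else "M",
    parameter = parameter,
    value_canonical = values
  )
}
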