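# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or textbook algorithms, never through the
# package's own code paths.

# Longest common substring between a probe and a reference (single string;
# any non-ACGT character never matches), by the classic dynamic programme,
# vectorized over reference positions.
lcs_one_strand <- function(probe, ref) {
  a <- utf8ToInt(probe)
  b <- utf8ToInt(ref)
  acgt <- utf8ToInt("ACGT")
  a[!(a %in% acgt)] <- -1L  # probe-side sentinel
  b[!(b %in% acgt)] <- -2L  # reference-side sentinel (never equal)
  n <- length(b)
  prev <- integer(n)
  best <- 0L
  for (i in seq_along(a)) {
    eq <- b == a[i]
    cur <- integer(n)
    if (any(eq)) {
      shifted <- c(0L, prev[-n])
      cur[eq] <- shifted[eq] + 1L
      best <- max(best, max(cur))
    }
    prev <- cur
  }
  best
}

revcomp_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Both-strand longest common substring of a probe against a set of
# transcripts (concatenated with a non-matching separator).
lcs_oracle <- function(probe, transcripts) {
  ref <- paste(toupper(transcripts), collapse = "X")
  max(lcs_one_strand(toupper(probe), ref),
      lcs_one_strand(revcomp_oracle(toupper(probe)), ref))
}

# Brute-force overlap clustering: all-pairs overlap coefficients plus a
# hand-rolled union-find. Returns component membership and whether each
# term has at least one >= theta partner.
overlap_cluster_oracle <- function(members, theta, method = "min") {
  nt <- length(members)
  parent <- seq_len(nt)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ov_fun <- function(a, b) {
    i <- length(intersect(a, b))
    if (method == "min") i / min(length(a), length(b))
    else i / length(union(a, b))
  }
  partner <- logical(nt)
  if (nt > 1) {
    for (i in seq_len(nt - 1)) {
      for (j in seq.int(i + 1, nt)) {
        if (ov_fun(members[[i]], members[[j]]) >= theta) {
          partner[i] <- partner[j] <- TRUE
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  membership <- vapply(seq_len(nt), find, 1L)
  list(membership = membership, has_partner = partner)
}

# Exhaustive triple loop over (human gene, mouse gene, reference pair).
crosstalk_oracle <- function(human_genes, mouse_genes, reference, orthology) {
  out <- list()
  for (h in unique(human_genes)) {
    for (m in unique(mouse_genes)) {
      hm <- orthology$human_symbol[orthology$mouse_symbol == m]
      if (length(hm) != 1) next
      for (r in seq_len(nrow(reference))) {
        p1 <- reference$gene_sym_1[r]
        p2 <- reference$gene_sym_2[r]
        if ((p1 == h && p2 == hm) || (p1 == hm && p2 == h)) {
          out[[length(out) + 1L]] <- paste(h, m, sep = "|")
        }
      }
    }
  }
  sort(unique(unlist(out)))
}

# Small-study convenience wrapper: a reduced design that keeps unit tests
# fast while preserving the 2-line / 4-animal / 3-region topology.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_genes_per_species = 40, probes_per_set = 5, seed = seed, ...)
  simulate_experiment(cfg, generate_references(cfg))
}

random_probe <- function(len = 25) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
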