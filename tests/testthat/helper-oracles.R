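## Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Exhaustive global-alignment oracle for tiny sequences: enumerates every
## alignment, maximises (matches - gaps) then matches.  Exponential;
## lengths <= 7 only.
enum_align <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- c(score = -Inf, matches = -Inf)
  rec <- function(i, j, matches, gaps) {
    if (i > length(ca) && j > length(cb)) {
      sc <- matches - gaps
      if (sc > best["score"] ||
          (sc == best["score"] && matches > best["matches"]))
        best <<- c(score = sc, matches = matches)
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, matches + (ca[i] == cb[j]), gaps)
    if (i <= length(ca)) rec(i + 1, j, matches, gaps + 1)
    if (j <= length(cb)) rec(i, j + 1, matches, gaps + 1)
    invisible(NULL)
  }
  rec(1L, 1L, 0L, 0L)
  list(score = unname(best["score"]), matches = unname(best["matches"]),
       identity = unname(best["matches"]) / min(length(ca), length(cb)))
}

## Slow scalar two-criterion Needleman-Wunsch oracle: explicit (score,
## matches) lexicographic DP, written independently of the package's
## single-objective encoding.
slow_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0, n + 1, m + 1)
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  for (i in 1:n) for (j in 1:m) {
    cand_s <- c(S[i, j] + (ca[i] == cb[j]), S[i, j + 1] - 1,
                S[i + 1, j] - 1)
    cand_m <- c(M[i, j] + (ca[i] == cb[j]), M[i, j + 1], M[i + 1, j])
    smax <- max(cand_s)
    S[i + 1, j + 1] <- smax
    M[i + 1, j + 1] <- max(cand_m[cand_s == smax])
  }
  M[n + 1, m + 1] / min(n, m)
}

## Brute-force greedy dereplication using slow_identity, mirroring the
## documented contract (length-descending, id-ascending, first phylotype
## whose representative matches at >= threshold).
oracle_dereplicate <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (p in seq_along(reps)) {
      if (slow_identity(seqs[i], reps[p]) >= threshold) {
        members[[p]] <- c(members[[p]], names(seqs)[i])
        placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[i])
      members[[length(reps)]] <- names(seqs)[i]
    }
  }
  list(representatives = unname(reps), members = members)
}

## Exhaustive set-logic oracle for the pangenome partition.
oracle_core <- function(presence, taxonomy) {
  orders <- unique(taxonomy$order)
  keep <- vapply(rownames(presence), function(cl) {
    all(vapply(orders, function(o)
      any(presence[cl, taxonomy$order == o]), logical(1)))
  }, logical(1))
  rownames(presence)[keep]
}

oracle_specific <- function(presence, taxonomy, mins) {
  fams <- unique(taxonomy$family)
  out <- list()
  for (f in fams) {
    out[[f]] <- Filter(function(cl) {
      holders <- taxonomy$family[presence[cl, ]]
      length(holders) >= mins[[f]] && all(holders == f)
    }, rownames(presence))
    out[[f]] <- as.character(out[[f]])
  }
  out
}

## Minimal hand-built community: explicit matrices, no preset randomness.
make_truth <- function(lineages, copies, rates, background = 0,
                       lengths = c(rpoB = 3000, amoA = 650)) {
  CommunityTruth(lineages, copies, rates, backgroundRpoB = background,
                 markerLengths = lengths)
}

single_lineage_truth <- function(markers = c(rpoB = 3000, amoA = 650),
                                 copies = c(rpoB = 1, amoA = 1),
                                 rates = c(rpoB = 1, amoA = 8),
                                 background = 0, cell = 1,
                                 guild = "AOA") {
  lin <- data.frame(name = "L1", family = "NS-delta",
                    order = "Nitrososphaerales", guild = guild,
                    cell_abundance = cell)
  gc <- matrix(copies[names(markers)], 1,
               dimnames = list("L1", names(markers)))
  er <- matrix(rates[names(markers)], 1,
               dimnames = list("L1", names(markers)))
  er[gc == 0] <- NA_real_
  make_truth(lin, gc, er, background, markers)
}

## Random ClusterMatrix generator for oracle comparisons.
random_cluster_matrix <- function(n_clusters, n_genomes, n_orders = 3,
                                  n_families = 5) {
  orders <- paste0("O", seq_len(n_orders))
  families <- paste0("F", seq_len(n_families))
  fam <- sample(families, n_genomes, replace = TRUE)
  ord <- orders[as.integer(factor(fam, levels = families)) %%
                  n_orders + 1L]
  p <- matrix(runif(n_clusters * n_genomes) < 0.3, n_clusters, n_genomes,
              dimnames = list(paste0("c", seq_len(n_clusters)),
                              paste0("g", seq_len(n_genomes))))
  p <- p[rowSums(p) > 0, , drop = FALSE]
  tx <- data.frame(genome = colnames(p), order = ord, family = fam,
                   stringsAsFactors = FALSE)
  ClusterMatrix(p, tx, annotated = sample(rownames(p),
                                          ceiling(nrow(p) / 4)))
}
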