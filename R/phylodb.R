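## Phylotype database construction: pairwise protein identity, greedy
## dereplication, and family assignment against a labelled reference panel.

## Needleman-Wunsch with linear gap penalty, run as a single DP that
## maximises the pair (alignment score = matches - gap columns, then number
## of matched residues).  Encoding: with C = min(n, m) + 1 > max possible
## matches, maximising V = (C + 1) * matches - C * gaps is exactly that
## lexicographic objective, and matches = V mod C.  The per-row recurrence
## f[j] = max(candidate[j], f[j-1] - C) is solved vectorised via
## h[j] = f[j] + j*C = cummax(candidate + j*C).
.alignStats <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  m <- length(cb)
  C <- min(n, m) + 1
  jC <- (0:m) * C
  prev <- -jC                        # row 0: j leading gaps
  js <- seq_len(m)
  for (i in seq_len(n)) {
    cand <- pmax(prev[js] + ifelse(cb == ca[i], C + 1, 0),  # diagonal
                 prev[js + 1L] - C)                          # gap in b
    h <- cummax(c(-i * C, cand + jC[js + 1L]))
    prev <- h - jC
  }
  V <- prev[m + 1L]
  matches <- V %% C
  list(matches = matches, score = (V - matches) / C, shorter = min(n, m))
}

#' Global-alignment identity between two protein sequences
#'
#' Computes a global (Needleman-Wunsch) alignment with linear gap penalty
#' (match +1, mismatch 0, gap -1) and returns the number of identically
#' aligned residues divided by the length of the shorter sequence (the
#' CD-HIT convention, under which substrings score 1).  Among equally
#' scoring alignments the one with the most identical residues is used, so
#' the result is deterministic and symmetric.
#'
#' @param a,b amino-acid strings (or `AAString`s), non-empty.
#' @return Identity in `[0, 1]`.
#' @examples
#' pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKV")  # 0.9
#' pairwiseIdentity("MKT", "MKTA")               # 1.0 (substring)
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
    stop("both sequences must be single non-empty strings")
  st <- .alignStats(a, b)
  st$matches / st$shorter
}

## Canonical processing order for greedy clustering: length descending,
## ties by id ascending.
.greedyOrder <- function(seqs) {
  order(-width(seqs), names(seqs), method = "radix")
}

#' Greedy identity-threshold dereplication of marker proteins
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by length
#' (descending, ties by id ascending) and each record joins the first
#' existing phylotype whose representative it matches at or above
#' `threshold` identity (see [pairwiseIdentity()]); otherwise it founds a
#' new phylotype.  Because of the ordering, each phylotype's representative
#' is its longest member (ties resolved to the lexicographically smallest
#' id), and the output is invariant to the input order of the records.
#'
#' @param records an [Biostrings::AAStringSet] with unique names (record
#'   ids).  An optional `marker` mcols column must be constant.
#' @param threshold identity threshold in `(0, 1]`; 1 collapses identical
#'   sequences (and substrings) only.
#' @param marker marker label for the output (defaults to the records'
#'   `marker` mcols column, or `"marker"`).
#' @return A [PhylotypeSet-class]; phylotype ids are
#'   `<marker>.pt<k>` in foundation order.
#' @examples
#' aa <- Biostrings::AAStringSet(c(s1 = "MKTAYIAK", s2 = "MKTAYIAK",
#'                                 s3 = "MKTAYIAR"))
#' dereplicate(aa, threshold = 1.0)
#' @export
dereplicate <- function(records, threshold = 1.0, marker = NULL) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (is.null(marker)) {
    mm <- mcols(records)$marker
    if (!is.null(mm)) {
      if (length(unique(mm)) > 1L)
        stop("records mix markers: ", paste(unique(mm), collapse = ", "))
      marker <- unique(mm)
    } else marker <- "marker"
  }
  if (length(records) == 0L) {
    return(new("PhylotypeSet", marker = marker, threshold = threshold,
               representatives = AAStringSet(),
               members = setNames(list(), character(0)),
               assignedFamily = character(0),
               bestRefIdentity = numeric(0)))
  }
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must carry unique names")
  ord <- .greedyOrder(records)
  seqs <- as.character(records)[ord]
  ids <- names(records)[ord]
  rep_seq <- character(0)
  rep_id <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (p in seq_along(rep_seq)) {
      if (pairwiseIdentity(seqs[i], rep_seq[p]) >= threshold) {
        members[[p]] <- c(members[[p]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_seq <- c(rep_seq, seqs[i])
      rep_id <- c(rep_id, ids[i])
      members[[length(rep_seq)]] <- ids[i]
    }
  }
  pt_ids <- sprintf("%s.pt%03d", marker, seq_along(rep_seq))
  reps <- AAStringSet(setNames(rep_seq, pt_ids))
  mcols(reps) <- DataFrame(representative_id = rep_id)
  new("PhylotypeSet", marker = marker, threshold = threshold,
      representatives = reps,
      members = setNames(members, pt_ids),
      assignedFamily = setNames(rep(NA_character_, length(pt_ids)),
                                pt_ids),
      bestRefIdentity = setNames(rep(NA_real_, length(pt_ids)), pt_ids))
}

#' Assign family labels to phylotypes by best reference identity
#'
#' Each phylotype representative is compared against a labelled reference
#' panel; the family of the best-identity reference is adopted when that
#' identity reaches `min_identity`, otherwise the phylotype stays
#' unassigned (its best identity is still recorded).  Identity ties are
#' broken by the lexicographically smallest reference id and reported via
#' `message()`.
#'
#' @param pset a [PhylotypeSet-class].
#' @param refs an [Biostrings::AAStringSet] of reference proteins with an
#'   mcols `family` column (all non-`NA`); same marker as `pset`.
#' @param min_identity assignment cutoff in `[0, 1]`; the default 0.85 is a
#'   configurable package choice (family assignment by "high sequence
#'   similarity" has no universal cutoff).
#' @return The input `PhylotypeSet` with `assignedFamily` and
#'   `bestRefIdentity` filled in.
#' @export
assignFamily <- function(pset, refs, min_identity = 0.85) {
  stopifnot(is(pset, "PhylotypeSet"))
  if (length(refs) == 0L)
    stop("reference panel is empty for marker ", pset@marker)
  fam <- mcols(refs)$family
  if (is.null(fam) || any(is.na(fam)) || any(!nzchar(fam)))
    stop("every reference record must carry a family label")
  mm <- mcols(refs)$marker
  if (!is.null(mm) && any(mm != pset@marker))
    stop("reference marker does not match phylotype marker ", pset@marker)
  ref_ord <- order(names(refs), method = "radix")  # deterministic ties
  refs <- refs[ref_ord]
  fam <- fam[ref_ord]
  rep_seqs <- as.character(pset@representatives)
  ref_seqs <- as.character(refs)
  for (i in seq_along(rep_seqs)) {
    idents <- vapply(ref_seqs, pairwiseIdentity, numeric(1),
                     a = rep_seqs[i])
    best <- max(idents)
    hits <- which(idents == best)
    if (length(hits) > 1L &&
        length(unique(fam[hits])) > 1L)
      message("family tie for ", names(rep_seqs)[i] %||%
                phylotypeIds(pset)[i], ": keeping reference ",
              names(refs)[hits[1]])
    pset@bestRefIdentity[i] <- best
    pset@assignedFamily[i] <-
      if (best >= min_identity) fam[hits[1]] else NA_character_
  }
  pset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phylotype table as TSV
#'
#' Columns: `phylotype_id`, `marker`, `representative_id`, `n_members`,
#' `assigned_family`, `best_ref_identity`.
#'
#' @param pset a [PhylotypeSet-class].
#' @param file output path.
#' @return The written data.frame, invisibly.
#' @export
writePhylotypeTable <- function(pset, file) {
  df <- data.frame(
    phylotype_id = phylotypeIds(pset),
    marker = pset@marker,
    representative_id =
      mcols(pset@representatives)$representative_id %||%
        phylotypeIds(pset),
    n_members = vapply(pset@members, length, 1L),
    assigned_family = pset@assignedFamily,
    best_ref_identity = pset@bestRefIdentity,
    stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a protein FASTA as named records for dereplication
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the record id and
#' attaches `marker`, `source` and optional `family` metadata.
#'
#' @param file FASTA path.
#' @param marker marker label for all records.
#' @param source `"assembly"` or `"reference"`.
#' @param family optional family labels (recycled); required for
#'   reference panels.
#' @return An [Biostrings::AAStringSet] with mcols `marker`, `source`,
#'   `family`.
#' @export
readProteinFasta <- function(file, marker,
                             source = c("assembly", "reference"),
                             family = NA_character_) {
  source <- match.arg(source)
  aa <- readAAStringSet(file)
  names(aa) <- sub("\\s.*$", "", names(aa))
  if (source == "reference" && all(is.na(family)))
    stop("reference records require family labels")
  mcols(aa) <- DataFrame(marker = marker, source = source,
                         family = rep_len(family, length(aa)))
  aa
}
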