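#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming one string into the other, computed by the
#' standard dynamic program (row-vectorized).
#'
#' @param a,b Strings over a shared alphabet.
#' @return Non-negative integer; 0 iff `a == b`.
#' @examples
#' levenshtein("AAAA", "AAAT") # 1
#' @export
levenshtein <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  m <- length(x)
  n <- length(y)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n
  jj <- 1:n
  for (i in 1:m) {
    cost <- as.integer(x[i] != y)
    t1 <- pmin(prev[-1L] + 1L, prev[-(n + 1L)] + cost)
    # cur[j] = min(i + j, min_{l<=j}(t1[l] + j - l)) via running minimum
    cur <- cummin(c(i, t1 - jj)) + 0:n
    prev <- cur
  }
  as.integer(prev[n + 1L])
}

#' Pairwise Levenshtein distance matrix
#'
#' @param seqs Named character vector of sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
levenshtein_matrix <- function(seqs) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- levenshtein(seqs[[i]], seqs[[j]])
    }
  }
  d
}

#' Percent identity from edit distance
#'
#' `100 * (1 - d(a, b) / max(nchar(a), nchar(b)))`.
#'
#' @inheritParams levenshtein
#' @return Percentage in `[0, 100]`; 100 for identical strings.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) == 0L && nchar(b) == 0L) {
    stop("percent identity is undefined for two empty sequences")
  }
  100 * (1 - levenshtein(a, b) / max(nchar(a), nchar(b)))
}

#' Substitution notation between two proteins
#'
#' For equal-length sequences with at most `max_subs` mismatches, returns
#' the comma-joined `<ref><position><candidate>` list in mature numbering
#' (e.g. `"T32I, S57A"`); otherwise the compact `#<edit distance>` form used
#' for length-divergent or highly diverged pairs. Identical sequences give
#' `""`.
#'
#' @param candidate,reference Amino-acid strings on the same numbering.
#' @param numbering_offset Leading residues excluded from mature numbering
#'   (1 when the sequences include the initiator Met).
#' @param max_subs Mismatch count above which the `#d` form is used.
#' @return A string.
#' @export
substitution_notation <- function(candidate, reference, numbering_offset = 0L,
                                  max_subs = 10L) {
  if (nchar(candidate) == nchar(reference)) {
    cc <- strsplit(candidate, "")[[1]]
    rr <- strsplit(reference, "")[[1]]
    diff <- which(cc != rr)
    if (length(diff) == 0L) return("")
    if (length(diff) <= max_subs) {
      return(paste0(rr[diff], diff - numbering_offset, cc[diff],
                    collapse = ", "))
    }
  }
  paste0("#", levenshtein(candidate, reference))
}

#' Apply a substitution notation to a reference sequence
#'
#' Inverse of [substitution_notation()] for the equal-length case: applying
#' the notation to the reference regenerates the candidate.
#'
#' @param reference Amino-acid string.
#' @param notation Comma-separated `<ref><position><new>` string.
#' @inheritParams substitution_notation
#' @return The substituted sequence.
#' @export
apply_substitution_notation <- function(reference, notation,
                                        numbering_offset = 0L) {
  if (!nzchar(notation)) return(reference)
  parts <- strsplit(notation, ",\\s*")[[1]]
  m <- regmatches(parts, regexec("^([A-Z])(\\d+)([A-Z])$", parts))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed substitution token: ", parts[bad][1])
  for (tok in m) {
    pos <- as.integer(tok[3]) + numbering_offset
    if (substr(reference, pos, pos) != tok[2]) {
      stop("reference residue at position ", tok[3], " is '",
           substr(reference, pos, pos), "', not '", tok[2], "'")
    }
    substr(reference, pos, pos) <- tok[4]
  }
  reference
}

#' Residue motif at mature positions 87-90
#'
#' The four residues at mature positions 87-90 — the motif that separates
#' H3.1/H3.2 (SAVM) from H3.3-type variants (AAIG) and is read by the
#' HIRA/Daxx deposition machinery.
#'
#' @param protein Amino-acid string.
#' @param numbering_offset Leading residues excluded from mature numbering.
#' @param at Mature position interval (default `c(87, 90)`).
#' @return 4-letter string, or `NA_character_` when the sequence is too
#'   short to cover the interval.
#' @export
motif_87_90 <- function(protein, numbering_offset = 0L, at = c(87L, 90L)) {
  lo <- at[1] + numbering_offset
  hi <- at[2] + numbering_offset
  if (nchar(protein) < hi) return(NA_character_)
  substr(protein, lo, hi)
}

#' Cluster protein variants and assign sequence groups
#'
#' Agglomerative clustering (default average linkage) of the pairwise
#' Levenshtein matrix of candidates plus references. The dendrogram is cut
#' into `n_groups` clusters (the cut is deepened when H3.1/H3.2 and H3.3
#' fall together): the cluster containing H3.1/H3.2 is the `H3.1-group`, the
#' cluster containing H3.3 the `H3.3-group`, and remaining clusters are
#' ranked by mean distance to H3.3 — nearest is `distant-A`, the rest
#' `distant-B`.
#'
#' @param proteins Named character vector of candidate proteins (or tibble
#'   with `name`, `protein` columns).
#' @param references Named reference proteins; must include an H3.1 or H3.2
#'   sequence and an H3.3 sequence (by name).
#' @param linkage `hclust` agglomeration method.
#' @param n_groups Number of clusters to cut.
#' @return A `hyb_grouping`: list with the `hclust` tree, distance matrix,
#'   and a `groups` tibble (`name`, `group`, `aa_dist_h33`, `is_reference`).
#' @export
cluster_variants <- function(proteins, references = h3_reference_proteins(),
                             linkage = c("average", "complete", "single"),
                             n_groups = 4L) {
  linkage <- match.arg(linkage)
  if (is.data.frame(proteins)) {
    proteins <- stats::setNames(proteins$protein, proteins$name)
  }
  h31_names <- intersect(c("H3.1", "H3.2"), names(references))
  if (!length(h31_names) || !"H3.3" %in% names(references)) {
    stop("references must include H3.1 (or H3.2) and H3.3 by name")
  }
  seqs <- c(references, proteins[setdiff(names(proteins), names(references))])
  if (length(seqs) < 2L) stop("need at least 2 sequences to cluster")
  d <- levenshtein_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  k <- min(n_groups, length(seqs))
  repeat {
    cut <- stats::cutree(hc, k = k)
    if (cut[h31_names[1]] != cut[["H3.3"]] || k >= length(seqs)) break
    k <- k + 1L
  }
  dist_h33 <- d[, "H3.3"]
  cluster_label <- character(max(cut))
  cluster_label[cut[h31_names[1]]] <- "H3.1-group"
  cluster_label[cut[["H3.3"]]] <- "H3.3-group"
  rest <- setdiff(seq_len(max(cut)), c(cut[h31_names[1]], cut[["H3.3"]]))
  if (length(rest)) {
    mean_d <- vapply(rest, function(cl) mean(dist_h33[cut == cl]), numeric(1))
    rest <- rest[order(mean_d)]
    cluster_label[rest[1]] <- "distant-A"
    if (length(rest) > 1L) cluster_label[rest[-1]] <- "distant-B"
  }
  groups <- tibble::tibble(
    name = names(seqs),
    group = cluster_label[cut],
    aa_dist_h33 = as.integer(dist_h33),
    is_reference = names(seqs) %in% names(references)
  )
  structure(list(hclust = hc, dist = d, groups = groups,
                 references = names(references), linkage = linkage),
            class = "hyb_grouping")
}

#' @export
print.hyb_grouping <- function(x, ...) {
  cat("<hyb_grouping> ", nrow(x$groups), " sequences, ", x$linkage,
      " linkage\n", sep = "")
  print(table(x$groups$group))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy hyb_grouping
#' @export
tidy.hyb_grouping <- function(x, ...) x$groups

#' Export a variant dendrogram as Newick
#'
#' @param grouping A [cluster_variants()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(grouping, path) {
  ape::write.tree(ape::as.phylo(grouping$hclust), file = path)
  invisible(path)
}

#' Classify the 3'-end structure downstream of a CDS
#'
#' Searches the `search_span` nt downstream of a CDS end (strand-aware,
#' clipped at the contig edge) first for a histone stem-loop — a 16-mer with
#' a perfectly self-complementary 6-bp stem and a 4-nt loop matching
#' `loop_pattern` — then for a polyadenylation signal (AATAAA or ATTAAA).
#' Stem-loop takes precedence; neither motif gives `NotDetected`.
#'
#' @param genome Genome as in [scan_genome()].
#' @param chrom Chromosome name.
#' @param cds_end Genomic 0-based position just past the CDS 3' end on the
#'   given strand (for `-` this is the *left* CDS boundary, `cds_start`).
#' @param strand `"+"` or `"-"`.
#' @param search_span Downstream span to search (nt).
#' @param loop_pattern Regex the 4-nt loop must match.
#' @return Tibble row: `three_prime_class` (`StemLoop` / `PolyA` /
#'   `NotDetected`), `motif_offset` (0-based offset of the match downstream
#'   of the CDS end, NA if none), `motif` (matched string).
#' @export
classify_three_prime_end <- function(genome, chrom, cds_end, strand = "+",
                                     search_span = 800L,
                                     loop_pattern = "^TT[TC]") {
  genome <- as_genome(genome)
  L <- length(genome[[chrom]])
  if (strand == "+") {
    lo <- min(cds_end, L)
    hi <- min(L, cds_end + search_span)
    seq <- as.character(Biostrings::subseq(genome[[chrom]], lo + 1L,
                                           width = hi - lo))
  } else {
    hi <- max(cds_end, 0L)
    lo <- max(0L, cds_end - search_span)
    seq <- revcomp_chr(as.character(
      Biostrings::subseq(genome[[chrom]], lo + 1L, width = hi - lo)
    ))
  }
  classify_downstream_seq(seq, loop_pattern = loop_pattern)
}

#' @rdname classify_three_prime_end
#' @param seq Downstream sequence, already strand-oriented.
#' @export
classify_downstream_seq <- function(seq, loop_pattern = "^TT[TC]") {
  sl <- find_stem_loop(seq, loop_pattern)
  if (!is.na(sl)) {
    return(tibble::tibble(three_prime_class = "StemLoop",
                          motif_offset = sl,
                          motif = substr(seq, sl + 1L, sl + 16L)))
  }
  pa <- regexpr("AATAAA|ATTAAA", seq)
  if (pa > 0L) {
    return(tibble::tibble(three_prime_class = "PolyA",
                          motif_offset = as.integer(pa) - 1L,
                          motif = substr(seq, pa, pa + 5L)))
  }
  tibble::tibble(three_prime_class = "NotDetected",
                 motif_offset = NA_integer_, motif = NA_character_)
}

## 0-based offset of the first stem-loop 16-mer, or NA.
find_stem_loop <- function(seq, loop_pattern = "^TT[TC]") {
  n <- nchar(seq)
  if (n < 16L) return(NA_integer_)
  starts <- 1:(n - 15L)
  stem1 <- substring(seq, starts, starts + 5L)
  loop <- substring(seq, starts + 6L, starts + 9L)
  stem2 <- substring(seq, starts + 10L, starts + 15L)
  ok <- grepl(loop_pattern, loop) & !grepl("N", stem1, fixed = TRUE) &
    stem2 == vapply(stem1, revcomp_chr, character(1), USE.NAMES = FALSE)
  if (!any(ok)) return(NA_integer_)
  as.integer(which(ok)[1] - 1L)
}

#' Build a per-candidate characterization report
#'
#' Assembles one row per candidate: closest reference (minimal amino-acid
#' edit distance; ties by minimal nucleotide distance when CDSs are given,
#' then reference order), edit distances, percent identity, substitution
#' notation versus the closest reference, the 87-90 motif, the sequence
#' group from [cluster_variants()], and — when genomic context is available —
#' the 3'-end structure class.
#'
#' @param candidates Tibble with `name`, `protein`, and optionally `cds`,
#'   `chrom`, `strand`, `orf_start`, `orf_end`.
#' @param references Named character vector of reference proteins.
#' @param reference_cds Optional named list/vector of reference CDSs for
#'   nucleotide distances.
#' @param genome Optional genome for 3'-end classification.
#' @param numbering_offset Numbering offset of candidate/reference proteins.
#' @param search_span Passed to [classify_three_prime_end()].
#' @return A tibble (one row per candidate) mirroring the report columns.
#' @export
build_report_table <- function(candidates, references = h3_reference_proteins(),
                               reference_cds = NULL, genome = NULL,
                               numbering_offset = 0L, search_span = 800L) {
  if (nrow(candidates) == 0L) {
    return(tibble::tibble(name = character(), closest_reference = character(),
                          aa_edit_distance = integer(),
                          nt_edit_distance = integer(),
                          percent_identity = numeric(),
                          substitutions = character(), motif_87_90 = character(),
                          group = character(), three_prime_class = character()))
  }
  grouping <- cluster_variants(
    stats::setNames(candidates$protein, candidates$name),
    references = references
  )
  group_of <- stats::setNames(grouping$groups$group, grouping$groups$name)
  rows <- purrr::pmap(
    list(seq_len(nrow(candidates))),
    function(i) {
      cand <- candidates[i, ]
      aa_d <- vapply(references, levenshtein, integer(1), a = cand$protein)
      nt_d <- rep(NA_integer_, length(references))
      if (!is.null(reference_cds) && "cds" %in% names(candidates) &&
          !is.na(cand$cds)) {
        shared <- names(references) %in% names(reference_cds)
        nt_d[shared] <- vapply(reference_cds[names(references)[shared]],
                               levenshtein, integer(1), a = cand$cds)
      }
      ord <- order(aa_d, ifelse(is.na(nt_d), .Machine$integer.max, nt_d),
                   seq_along(references))
      best <- ord[1]
      tp <- if (!is.null(genome) && all(c("chrom", "strand") %in%
                                        names(candidates))) {
        cds_end <- if (cand$strand == "+") cand$orf_end else cand$orf_start
        classify_three_prime_end(genome, cand$chrom, cds_end, cand$strand,
                                 search_span = search_span)$three_prime_class
      } else NA_character_
      tibble::tibble(
        name = cand$name,
        closest_reference = names(references)[best],
        aa_edit_distance = unname(aa_d[best]),
        nt_edit_distance = unname(nt_d[best]),
        percent_identity = percent_identity(cand$protein, references[[best]]),
        substitutions = substitution_notation(cand$protein, references[[best]],
                                              numbering_offset),
        motif_87_90 = motif_87_90(cand$protein, numbering_offset),
        group = unname(group_of[cand$name]),
        three_prime_class = tp
      )
    }
  )
  dplyr::bind_rows(rows)
}
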