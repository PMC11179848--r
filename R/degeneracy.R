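# Codon degeneracy classification of CDS positions: a site is 4-fold
# degenerate if every base yields the same amino acid, 0-fold if every
# change alters it.

# Lookup table over 64 codons x 3 positions, built once per session
# from the standard genetic code by substituting all four bases at each
# position.
.codon_fold_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(code)
    res <- matrix(NA_character_, 64L, 3L, dimnames = list(codons, NULL))
    for (cd in codons) {
      for (k in 1:3) {
        aa <- code[[cd]]
        alts <- vapply(bases, function(b) {
          mut <- cd
          substr(mut, k, k) <- b
          code[[mut]]
        }, "")
        n_same <- sum(alts == aa)  # includes the codon's own base
        res[cd, k] <- switch(as.character(n_same),
                             "1" = "0", "2" = "2", "4" = "4", "other")
      }
    }
    tab <<- res
    tab
  }
})

#' Classify CDS positions by codon degeneracy
#'
#' For every complete in-frame codon of every transcript, assigns each
#' of its three positions a fold class by substituting all four bases:
#' `"4"` if all substitutions are synonymous, `"0"` if none are, `"2"`
#' if the site is two-fold degenerate, `"other"` for three-fold sites
#' (the isoleucine family). Positions are mapped back to genome
#' coordinates strand-aware. Transcripts whose spliced CDS length is
#' not a multiple of 3 or that contain an internal stop codon are
#' skipped with a log entry.
#'
#' @param genome A `Biostrings::DNAStringSet` (or FASTA path) holding
#'   the contig sequences.
#' @param cds Either a GFF3 file path (read with rtracklayer when
#'   available) or a data frame with columns `seqid`, `start`, `end`,
#'   `strand`, `transcript_id` describing CDS segments (1-based
#'   inclusive).
#' @return A tibble (`degeneracy_map`): `contig`, `pos`, `transcript`,
#'   `codon`, `codon_pos` (1-3), `fold` (`"0"`, `"2"`, `"4"`,
#'   `"other"`). Attribute `skipped` lists skipped transcripts and
#'   reasons.
#' @export
classify_degeneracy <- function(genome, cds) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(cds)) {
    cds <- .read_gff3_cds(cds)
  }
  cds <- tibble::as_tibble(cds)
  need <- c("seqid", "start", "end", "strand", "transcript_id")
  stopifnot(all(need %in% names(cds)))

  fold_tab <- .codon_fold_table()
  out <- list()
  skipped <- list()
  for (tx in unique(cds$transcript_id)) {
    seg <- cds[cds$transcript_id == tx, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    chrom <- seg$seqid[1L]
    if (!chrom %in% names(genome)) {
      skipped[[tx]] <- "contig not in genome"
      next
    }
    gpos <- unlist(mapply(seq.int, seg$start, seg$end, SIMPLIFY = FALSE))
    if (anyDuplicated(gpos)) {
      skipped[[tx]] <- "overlapping CDS segments"
      next
    }
    seq_fwd <- paste(vapply(seq_len(nrow(seg)), function(i) {
      as.character(Biostrings::subseq(genome[[chrom]],
                                      seg$start[i], seg$end[i]))
    }, ""), collapse = "")
    minus <- seg$strand[1L] == "-"
    cds_seq <- if (minus) {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_fwd)))
    } else seq_fwd
    cds_pos <- if (minus) rev(gpos) else gpos

    L <- nchar(cds_seq)
    if (L %% 3 != 0) {
      skipped[[tx]] <- "CDS length not a multiple of 3"
      next
    }
    codons <- substring(cds_seq, seq(1L, L, 3L), seq(3L, L, 3L))
    if (any(!codons %in% rownames(fold_tab))) {
      skipped[[tx]] <- "ambiguous bases in CDS"
      next
    }
    aa_stop <- Biostrings::GENETIC_CODE[codons] == "*"
    if (any(aa_stop[-length(aa_stop)])) {
      skipped[[tx]] <- "internal stop codon"
      next
    }
    fold <- as.vector(t(fold_tab[codons, , drop = FALSE]))
    out[[tx]] <- tibble::tibble(
      contig = chrom,
      pos = cds_pos,
      transcript = tx,
      codon = rep(codons, each = 3L),
      codon_pos = rep(1:3, times = length(codons)),
      fold = fold
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(contig = character(), pos = integer(),
                   transcript = character(), codon = character(),
                   codon_pos = integer(), fold = character())
  }
  attr(res, "skipped") <- skipped
  res
}

# minimal GFF3 CDS extraction; prefers rtracklayer when installed
.read_gff3_cds <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    df <- df[df$type == "CDS", , drop = FALSE]
    parent <- if (!is.null(df$Parent)) {
      vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
             "")
    } else df$ID
    return(tibble::tibble(
      seqid = as.character(df$seqnames),
      start = df$start,
      end = df$end,
      strand = as.character(df$strand),
      transcript_id = parent))
  }
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  names(tab)[1:9] <- c("seqid", "source", "type", "start", "end",
                       "score", "strand", "phase", "attributes")
  tab <- tab[tab$type == "CDS", , drop = FALSE]
  parent <- sub(".*Parent=([^;]+).*", "\\1", tab$attributes)
  tibble::tibble(seqid = tab$seqid, start = tab$start, end = tab$end,
                 strand = tab$strand, transcript_id = parent)
}

#' Degeneracy map from synthetic effect classes
#'
#' Synthetic cohorts carry effect-class truth instead of an annotated
#' genome; this helper derives the class-based analogue of a degeneracy
#' map for [pi_ratio_0fold_4fold()]: synonymous sites stand in for
#' 4-fold sites, deleterious and LoF sites for 0-fold sites.
#'
#' @param dataset A `cohort_dataset`.
#' @return A tibble `contig`, `pos`, `fold`.
#' @export
effect_class_degmap <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  s <- dataset$sites
  fold <- dplyr::case_when(
    s$effect_class == "synonymous" ~ "4",
    s$effect_class %in% c("deleterious", "lof") ~ "0",
    TRUE ~ "other"
  )
  tibble::tibble(contig = s$contig, pos = s$pos, fold = fold)
}
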