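#' Construct a protein record
#'
#' @param id Protein/gene identifier.
#' @param sequence Amino-acid sequence (one-letter codes; trailing `*`
#'   stripped).
#' @param alphabet Allowed residue letters; defaults to the 20 canonical
#'   amino acids. Toy proteomes may use a smaller alphabet.
#' @param strict Error on non-alphabet letters (otherwise drop with warning).
#' @return A `protein_record` with fields `id`, `sequence`, `aa_freq`.
#' @export
protein_record <- function(id, sequence, alphabet = CANONICAL_AA,
                           strict = TRUE) {
  fr <- aa_frequencies(sequence, alphabet = alphabet, strict = strict)
  structure(list(id = id, sequence = sequence, aa_freq = fr),
            class = "protein_record")
}

#' Residue frequencies of an amino-acid sequence
#'
#' Frequencies are counts over length, so they sum to 1 and feed directly
#' into the protein-specific sink reaction ([make_protein_sink()]).
#'
#' @param sequence Amino-acid string; a trailing stop (`*`) is stripped.
#' @param alphabet Allowed residue letters.
#' @param strict If `TRUE`, any letter outside `alphabet` is an error; if
#'   `FALSE` such letters are dropped with a warning.
#' @return Named numeric vector of frequencies (only residues present).
#' @export
aa_frequencies <- function(sequence, alphabet = CANONICAL_AA, strict = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sub("\\*$", "", sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    if (strict) {
      stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "))
    }
    warning("dropping non-canonical residue letter(s): ",
            paste(bad, collapse = ", "))
    chars <- chars[chars %in% alphabet]
    if (!length(chars)) stop("no canonical residues left after dropping")
  }
  tab <- table(chars)
  stats::setNames(as.numeric(tab) / length(chars), names(tab))
}

# standard genetic code on the DNA alphabet (TCAG enumeration, third base
# fastest); Biostrings::GENETIC_CODE is the cross-check in the test suite
genetic_code_dna <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  stats::setNames(aas, codons)
}

split_codons <- function(cds) {
  cds <- toupper(chartr("U", "T", cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Build a codon-usage table from a highly-expressed reference set
#'
#' Codon counts are aggregated over the reference CDSs (conventionally the
#' ribosomal-protein genes); relative adaptiveness is
#' `w = count / max count among synonymous codons`. Codons unused in the
#' reference receive a small pseudo-weight so downstream geometric means
#' never collapse to zero.
#'
#' @param reference_cds Character vector of in-frame CDS sequences.
#' @param pseudo_w Relative adaptiveness assigned to zero-count codons.
#' @param strict Error on internal stop codons in the reference.
#' @return A `codon_usage_table`: tibble with `codon`, `aa`, `count`, `w`.
#' @export
build_codon_usage <- function(reference_cds, pseudo_w = 0.01, strict = FALSE) {
  if (length(reference_cds) == 0L) stop("empty reference CDS set")
  code <- genetic_code_dna()
  counts <- stats::setNames(numeric(length(code)), names(code))
  for (cds in reference_cds) {
    cod <- split_codons(cds)
    if (strict) {
      internal <- cod[-length(cod)]
      if (any(code[internal] == "*")) stop("internal stop codon in reference CDS")
    }
    cod <- cod[cod %in% names(code)]
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  aa <- unname(code)
  w <- numeric(length(counts))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    mx <- max(counts[idx])
    w[idx] <- if (mx > 0) counts[idx] / mx else 1
  }
  w[w == 0] <- pseudo_w
  tibble::tibble(codon = names(counts), aa = aa,
                 count = unname(counts), w = w) -> tab
  class(tab) <- c("codon_usage_table", class(tab))
  tab
}

#' Codon adaptation index
#'
#' Geometric mean of relative adaptiveness `w` over the counted codons of a
#' CDS. The `sharp-li` dialect excludes Met, Trp and stop codons from the
#' mean (single-codon amino acids carry no usage information); the
#' `emboss` dialect keeps Met and Trp and excludes only stops.
#'
#' @param cds In-frame CDS sequence.
#' @param table A `codon_usage_table` from [build_codon_usage()].
#' @param dialect `"sharp-li"` (default) or `"emboss"`.
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, table, dialect = c("sharp-li", "emboss")) {
  dialect <- match.arg(dialect)
  cod <- split_codons(cds)
  w <- stats::setNames(table$w, table$codon)
  aa <- stats::setNames(table$aa, table$codon)
  cod <- cod[cod %in% names(w)]
  excl_aa <- if (dialect == "sharp-li") c("M", "W", "*") else "*"
  cod <- cod[!(aa[cod] %in% excl_aa)]
  if (!length(cod)) stop("no codons left after exclusions; CDS too short")
  exp(mean(log(w[cod])))
}

#' Extract the 42-nt folding window at a gene start
#'
#' The window runs from position -4 to +38 relative to the translation
#' start (biological coordinates: no position 0; +1 is the first base of
#' the start codon), i.e. 4 nt of 5' context followed by the first 38 nt
#' of the CDS. The caller supplies plus-strand sequence with a 1-based
#' start offset; insufficient context yields a missing window, not an
#' error, so pipelines continue.
#'
#' @param genomic_context Plus-strand nucleotide string containing the start.
#' @param start 1-based offset of the first base of the start codon within
#'   `genomic_context`.
#' @param gene_id Identifier carried through to the result.
#' @return A `gene_start_window`: list with `gene_id`, `window_sequence`
#'   (42 nt or `NA`), `folding_energy` (`NA` until computed).
#' @export
gene_start_window <- function(genomic_context, start, gene_id = NA_character_) {
  stopifnot(is.character(genomic_context), length(genomic_context) == 1L)
  n <- nchar(genomic_context)
  win <- if (start >= 5L && start + 37L <= n) {
    substr(genomic_context, start - 4L, start + 37L)
  } else {
    NA_character_
  }
  structure(list(gene_id = gene_id, window_sequence = win,
                 folding_energy = NA_real_),
            class = "gene_start_window")
}

#' Minimum free energy of a gene-start window
#'
#' Folding energy is an input covariate, not something this package
#' predicts: supply either a folding `engine` (a function mapping a
#' nucleotide string to an MFE in kcal/mol, e.g. [rnafold_engine()]) or a
#' precomputed lookup `table` (named numeric, gene id -> energy). With
#' neither available the value stays missing and the pipeline continues.
#'
#' @param window A `gene_start_window`.
#' @param engine Optional function `(sequence) -> energy`.
#' @param table Optional named numeric vector of precomputed energies.
#' @return The window with `folding_energy` filled (`NA` if unavailable).
#' @export
folding_energy <- function(window, engine = NULL, table = NULL) {
  stopifnot(inherits(window, "gene_start_window"))
  if (!is.null(table) && !is.na(window$gene_id) &&
      window$gene_id %in% names(table)) {
    window$folding_energy <- unname(table[[window$gene_id]])
    return(window)
  }
  if (!is.null(engine) && !is.na(window$window_sequence)) {
    window$folding_energy <- engine(window$window_sequence)
    return(window)
  }
  window$folding_energy <- NA_real_
  window
}

#' Folding engine backed by the RNAfold command-line program
#'
#' Returns a callable suitable for [folding_energy()]'s `engine` argument,
#' or `NULL` when RNAfold is not on the PATH (callers then fall back to a
#' precomputed table or a missing value).
#'
#' @return Function `(sequence) -> mfe kcal/mol`, or `NULL`.
#' @export
rnafold_engine <- function() {
  if (!nzchar(Sys.which("RNAfold"))) return(NULL)
  function(sequence) {
    out <- system2("RNAfold", c("--noPS"), input = chartr("T", "U", sequence),
                   stdout = TRUE)
    line <- out[length(out)]
    m <- regmatches(line, regexpr("\\(\\s*-?[0-9.]+\\)$", line))
    if (!length(m)) return(NA_real_)
    as.numeric(gsub("[() ]", "", m))
  }
}

#' Read precomputed folding energies from TSV (gene_id, energy)
#'
#' @param path TSV with columns `gene_id` and `energy`.
#' @return Named numeric vector.
#' @export
read_folding_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "energy") %in% names(tab)))
  stats::setNames(as.numeric(tab$energy), tab$gene_id)
}

#' Read a proteome FASTA into protein records
#'
#' @param path FASTA path.
#' @param alphabet,strict Passed to [protein_record()].
#' @return Named list of `protein_record`s.
#' @export
read_proteome_fasta <- function(path, alphabet = CANONICAL_AA, strict = TRUE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA files")
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  recs <- lapply(seq_along(seqs), function(i) {
    protein_record(ids[i], as.character(seqs[[i]]), alphabet = alphabet,
                   strict = strict)
  })
  stats::setNames(recs, ids)
}

#' Write protein records to FASTA
#'
#' @param proteome Named list of `protein_record`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  lines <- unlist(lapply(proteome, function(p) c(paste0(">", p$id), p$sequence)))
  writeLines(lines, path)
  invisible(path)
}
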