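#' The canonical exon-3 SNP panel
#'
#' Eight biallelic SNPs within exon 3 of the X-linked cone opsin genes
#' (*OPN1LW*/*OPN1MW*) define the haplotype space used throughout this
#' package. The panel is shipped as a TSV so the same machinery applies to
#' *OPN1MW* exon-3 haplotypes. Column `alias` records an alternative dbSNP
#' spelling seen in the literature (rs94930 is also written rs949930).
#' Coding SNPs carry the codon number and the amino acid encoded by each
#' allele; synonymous SNPs have `NA` amino acids and are ignored by
#' [translate_haplotype()].
#'
#' @return A data frame with columns `snp_id`, `alias`, `position`,
#'   `allele1`, `allele2`, `codon`, `aa1`, `aa2`, one row per SNP in
#'   canonical order (position 1 to 8).
#' @export
#' @examples
#' snp_panel()
snp_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    path <- system.file("extdata", "snp_panel.tsv", package = "opsinmyopia",
                        mustWork = TRUE)
    p <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
    stopifnot(nrow(p) == 8L, identical(p$position, 1:8))
    .panel_cache$panel <- p
  }
  .panel_cache$panel
}

.panel_cache <- new.env(parent = emptyenv())

# Resolve a SNP identifier (or alias) to its panel row index.
.snp_index <- function(snp_id) {
  p <- snp_panel()
  i <- match(snp_id, p$snp_id)
  if (is.na(i)) i <- match(snp_id, p$alias)
  if (is.na(i)) {
    stop("unknown SNP id '", snp_id, "'; panel SNPs are: ",
         paste(p$snp_id, collapse = ", "), call. = FALSE)
  }
  i
}

#' Parse and validate an exon-3 haplotype string
#'
#' A haplotype is written as a bare 8-character nucleotide string giving the
#' allele at each panel SNP in canonical order (rs94930, rs713, rs731614,
#' rs5986963, rs5986964, rs149897670, rs145009674, rs155715655). Parsing is
#' case-insensitive and trims surrounding whitespace.
#'
#' In strict mode (the default) every allele must be one of the two alleles
#' defined for its position; an off-panel allele is an error naming the
#' position and SNP. In lenient mode off-panel alleles are retained and
#' reported in the `off_panel` attribute of the result.
#'
#' @param text Character vector of 8-character haplotype strings.
#' @param strict Logical; reject off-panel alleles (default `TRUE`).
#' @return An uppercase character vector of validated haplotypes. In lenient
#'   mode, attribute `off_panel` is a data frame (`hap`, `position`,
#'   `snp_id`, `allele`) listing retained off-panel alleles (zero rows if
#'   none).
#' @export
#' @examples
#' parse_haplotype("aacggtgg")
#' parse_haplotype("GCGGGGAT", strict = FALSE)
parse_haplotype <- function(text, strict = TRUE) {
  if (!is.character(text) || length(text) == 0) {
    stop("'text' must be a non-empty character vector", call. = FALSE)
  }
  hap <- toupper(trimws(text))
  bad_len <- nchar(hap) != 8L
  if (any(bad_len)) {
    stop("haplotype must be exactly 8 characters, got '",
         hap[bad_len][1L], "' (", nchar(hap[bad_len][1L]), ")", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(hap, "")), ncol = 8L, byrow = TRUE)
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    bad <- chars[!chars %in% c("A", "C", "G", "T")][1L]
    stop("non-nucleotide character '", bad, "' in haplotype", call. = FALSE)
  }
  p <- snp_panel()
  off <- which(t(chars) != rep(p$allele1, length(hap)) &
               t(chars) != rep(p$allele2, length(hap)))
  if (length(off)) {
    pos <- (off - 1L) %% 8L + 1L
    idx <- (off - 1L) %/% 8L + 1L
    if (strict) {
      stop("off-panel allele '", t(chars)[off[1L]], "' at position ", pos[1L],
           " (", p$snp_id[pos[1L]], " allows only ", p$allele1[pos[1L]], "/",
           p$allele2[pos[1L]], ") in haplotype '", hap[idx[1L]], "'",
           call. = FALSE)
    }
    attr(hap, "off_panel") <- data.frame(
      hap = hap[idx], position = pos, snp_id = p$snp_id[pos],
      allele = t(chars)[off], stringsAsFactors = FALSE)
  } else if (!strict) {
    attr(hap, "off_panel") <- data.frame(
      hap = character(), position = integer(), snp_id = character(),
      allele = character(), stringsAsFactors = FALSE)
  }
  hap
}

#' Translate a nucleotide haplotype to its amino-acid haplotype
#'
#' The five coding SNPs determine the residues at opsin protein positions
#' 153, 171, 174, 178 and 180 (rs713: A=M/C=L; rs5986963: A=I/G=V;
#' rs149897670: C=A/T=V; rs145009674: A=I/G=V; rs155715655: G=A/T=S).
#' The three synonymous SNPs are ignored, so haplotypes differing only at
#' those positions translate identically.
#'
#' @param hap Character vector of 8-character haplotype strings (validated
#'   with [parse_haplotype()] internally).
#' @return Character vector of 5-letter amino-acid haplotypes
#'   (positions 153/171/174/178/180).
#' @export
#' @examples
#' translate_haplotype("AACGGTGG") # "MVVVA"
#' translate_haplotype(c("GCGATCAT", "AAGGGCAT"))
translate_haplotype <- function(hap) {
  hap <- parse_haplotype(hap, strict = FALSE)
  p <- snp_panel()
  coding <- p[!is.na(p$aa1), ]
  coding <- coding[order(coding$codon), ]
  out <- character(length(hap))
  for (j in seq_len(nrow(coding))) {
    a <- substr(hap, coding$position[j], coding$position[j])
    res <- ifelse(a == coding$allele1[j], coding$aa1[j],
           ifelse(a == coding$allele2[j], coding$aa2[j], NA_character_))
    if (anyNA(res)) {
      bad <- which(is.na(res))[1L]
      stop("cannot translate '", hap[bad], "': allele '",
           substr(hap[bad], coding$position[j], coding$position[j]),
           "' at coding SNP ", coding$snp_id[j], " (codon ",
           coding$codon[j], ") is off-panel", call. = FALSE)
    }
    out <- paste0(out, res)
  }
  out
}

#' Enumerate the minigene haplotype space
#'
#' Generates every exon-3 haplotype in which the six unconstrained SNPs vary
#' freely over their two alleles while the (rs5986963, rs5986964) pair takes
#' only its two observed joint states, (A,T) or (G,G). This is the set of
#' 128 haplotypes assayed in the minigene splicing experiment.
#'
#' @return A lexicographically sorted character vector of 128 haplotype
#'   strings, without duplicates.
#' @export
#' @examples
#' length(enumerate_minigene_haplotypes())
enumerate_minigene_haplotypes <- function() {
  p <- snp_panel()
  free <- c(1L, 2L, 3L, 6L, 7L, 8L)
  alleles <- lapply(free, function(i) sort(c(p$allele1[i], p$allele2[i])))
  names(alleles) <- paste0("p", free)
  grid <- expand.grid(c(alleles, list(pair = c("AT", "GG"))),
                      stringsAsFactors = FALSE)
  haps <- paste0(grid$p1, grid$p2, grid$p3,
                 substr(grid$pair, 1, 1), substr(grid$pair, 2, 2),
                 grid$p6, grid$p7, grid$p8)
  sort(unique(haps))
}

#' Allele carried at a given panel SNP
#'
#' @param hap Character vector of haplotype strings.
#' @param snp_id A single SNP identifier from the canonical panel (aliases
#'   accepted).
#' @return Character vector of single nucleotides, one per haplotype.
#' @export
#' @examples
#' allele_at("AACGGTGG", "rs145009674") # "G"
allele_at <- function(hap, snp_id) {
  hap <- parse_haplotype(hap, strict = FALSE)
  attributes(hap) <- NULL
  i <- .snp_index(snp_id)
  substr(hap, i, i)
}
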