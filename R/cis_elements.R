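# Promoter cis-regulatory element scanning against a small bundled
# dictionary of IUPAC consensus sites (the ten elements most commonly seen
# in WRKY promoter surveys). Both strands are scanned; minus-strand hits are
# reported in plus-strand coordinates of the promoter.

IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Bundled cis-regulatory element dictionary
#'
#' Ten common promoter elements with their IUPAC consensi: the WRKY-binding
#' W-box (YTGACY, i.e. (C/T)TGAC(T/C)), the light-responsive G-box and Sp1,
#' the hormone-responsive CGTCA-motif, ERF site and ABRE, the
#' endosperm-expression Skn-1 motif, the stress-responsive TC-rich repeat,
#' the drought-responsive MBS and the heat-shock element HSE. Users may
#' supply their own dictionary as a data frame of the same shape.
#'
#' @return Data frame with columns `name`, `consensus`, `description`.
#' @export
cis_element_dictionary <- function() {
  data.frame(
    name = c("W-box", "G-box", "Sp1", "CGTCA-motif", "ERF", "ABRE",
             "Skn-1", "TC-rich", "MBS", "HSE"),
    consensus = c("YTGACY", "CACGTG", "GGGCGG", "CGTCA", "ATTTCAAA",
                  "TACGTG", "GTCAT", "ATTTTCTTCA", "CAACTG", "AAAAAATTTC"),
    description = c("WRKY binding site, fungal elicitor responsive",
                    "light responsive", "light responsive",
                    "MeJA responsive", "ethylene responsive",
                    "abscisic acid responsive", "endosperm expression",
                    "defense and stress responsive", "MYB drought responsive",
                    "heat stress responsive"),
    stringsAsFactors = FALSE)
}

iupac_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad))
    stop_format("consensus contains non-IUPAC codes: ", paste(bad, collapse = ","))
  paste0(vapply(chars, function(ch) {
    ex <- IUPAC_DNA[[ch]]
    if (nchar(ex) == 1) ex else paste0("[", ex, "]")
  }, ""), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all (possibly overlapping) match starts of a fixed-width pattern
regex_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan a promoter for cis-regulatory elements
#'
#' Matches every element's IUPAC consensus on both strands. Minus-strand
#' hits are mapped back to plus-strand coordinates; the reported `match` is
#' always the plus-strand substring (whose reverse complement satisfies the
#' consensus for minus-strand hits). A site matched identically on both
#' strands (a palindromic consensus) is reported once, on the plus strand.
#' `N` in the promoter matches nothing.
#'
#' @param promoter DNA string over A, C, G, T, N.
#' @param dictionary Element dictionary, defaulting to
#'   [cis_element_dictionary()].
#' @return Data frame sorted by position with columns `element`, `start`
#'   (1-based, plus-strand), `strand` (`"+"` or `"-"`) and `match`.
#' @examples
#' scan_cis_elements("AATTGACCAA")   # W-box on the plus strand
#' @export
scan_cis_elements <- function(promoter, dictionary = cis_element_dictionary()) {
  promoter <- toupper(promoter)
  bad <- setdiff(strsplit(promoter, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop_format("promoter contains non-nucleotide characters: ",
                paste(unique(bad), collapse = ","))
  L <- nchar(promoter)
  rc <- revcomp(promoter)
  hits <- list()
  for (k in seq_len(nrow(dictionary))) {
    cons <- dictionary$consensus[k]
    w <- nchar(cons)
    rx <- iupac_regex(cons)
    for (s in regex_starts(promoter, rx)) {
      hits[[length(hits) + 1L]] <- data.frame(
        element = dictionary$name[k], start = s, strand = "+",
        match = substr(promoter, s, s + w - 1L), stringsAsFactors = FALSE)
    }
    for (s in regex_starts(rc, rx)) {
      plus_start <- L - (s + w - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        element = dictionary$name[k], start = plus_start, strand = "-",
        match = substr(promoter, plus_start, plus_start + w - 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(element = character(), start = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  # a palindromic site matches at the same interval on both strands: one site
  out <- out[order(out$start, out$element, out$strand), , drop = FALSE]
  out <- out[!duplicated(out[, c("element", "start")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
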