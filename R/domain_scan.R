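# WRKY domain detection: the DNA-binding domain of a WRKY transcription
# factor is ~60 residues, made of the conserved heptapeptide (WRKYGQK or a
# close variant) followed by a zinc finger whose four metal-coordinating
# residues are either C..C..H..H (C2H2) or C..C..H..C (C2HC), with
# characteristic spacer lengths between them. Scanning is anchored on the
# heptapeptide and then looks downstream for the finger.

#' Default heptapeptide variant set
#'
#' The canonical WRKYGQK heptapeptide plus the variant spellings observed in
#' the family (WRKYGKK, WRKYDQK, WRKYDHK and the WKKY- forms that appear in
#' published family tables).
#' @return Character vector of 7-mers.
#' @export
wrky_variants <- function() {
  c("WRKYGQK", "WRKYGKK", "WRKYDQK", "WRKYDHK", "WKKYDHK", "WKKYDQK")
}

#' Allowed zinc-finger spacing ranges
#'
#' Defines, per finger type, which spacer lengths (number of residues between
#' consecutive coordinating residues) count as a WRKY zinc finger, plus the
#' maximum allowed gap between the end of the heptapeptide and the first
#' cysteine. The `"default"` profile accepts the spacings actually observed
#' in family tables (C2H2: C-X4/5-C-X22..24-H-X1-H; C2HC: C-X7-C-X22/23-H-X1-C);
#' the `"strict"` profile narrows the C2H2 second spacer to 22-23.
#'
#' @param profile `"default"` or `"strict"`.
#' @param c2h2_n1,c2h2_n2,c2hc_n1,c2hc_n2 Optional integer vectors overriding
#'   the allowed first/second spacer lengths per finger type. The first C2H2
#'   spacer may be widened up to 7.
#' @param max_gap Maximum number of residues between the heptapeptide end and
#'   the first coordinating cysteine (default 60, the approximate size of the
#'   whole WRKY domain).
#' @return A `pattern_space` list with elements `C2H2`, `C2HC` (each with
#'   `n1`, `n2`, `n3`) and `max_gap`.
#' @export
wrky_pattern_space <- function(profile = c("default", "strict"),
                               c2h2_n1 = NULL, c2h2_n2 = NULL,
                               c2hc_n1 = NULL, c2hc_n2 = NULL,
                               max_gap = 60) {
  profile <- match.arg(profile)
  ps <- list(
    C2H2 = list(n1 = c2h2_n1 %||% 4:5,
                n2 = c2h2_n2 %||% (if (profile == "default") 22:24 else 22:23),
                n3 = 1L),
    C2HC = list(n1 = c2hc_n1 %||% 7L,
                n2 = c2hc_n2 %||% 22:23,
                n3 = 1L),
    max_gap = max_gap
  )
  if (max_gap <= 0) stop_config("max_gap must be positive")
  if (any(ps$C2H2$n1 > 7)) stop_config("C2H2 first spacer may be widened at most to 7")
  if (!length(ps$C2H2$n1) || !length(ps$C2H2$n2) ||
      !length(ps$C2HC$n1) || !length(ps$C2HC$n2))
    stop_config("spacing ranges must be non-empty")
  structure(ps, class = "pattern_space")
}

#' Find heptapeptide anchors in a protein sequence
#'
#' Reports every occurrence of any variant in `variant_set`, including
#' overlapping occurrences, sorted by position. The ambiguity code `X` never
#' matches a heptapeptide position.
#'
#' @param sequence Amino-acid string.
#' @param variant_set Character vector of 7-mers; defaults to
#'   [wrky_variants()].
#' @return Data frame with columns `start` (1-based) and `variant`; zero rows
#'   when nothing matches.
#' @examples
#' find_heptapeptides("AAAWRKYGQKAAA")
#' @export
find_heptapeptides <- function(sequence, variant_set = wrky_variants()) {
  check_protein_sequence(sequence)
  if (!length(variant_set)) stop_config("variant_set must be non-empty")
  if (any(nchar(variant_set) != 7)) stop_config("variants must be 7-mers")
  hits <- data.frame(start = integer(), variant = character(),
                     stringsAsFactors = FALSE)
  for (v in sort(variant_set)) {    # sorted: output independent of set order
    m <- gregexpr(v, sequence, fixed = TRUE)[[1]]
    if (m[1] != -1)
      hits <- rbind(hits, data.frame(start = as.integer(m), variant = v,
                                     stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$variant), , drop = FALSE]
}

# check a candidate quadruple with spacers (n1, n2, n3) starting at c1;
# returns TRUE when the coordinating residues are present
match_finger_at <- function(chars, c1, n1, n2, n3, last) {
  c2 <- c1 + n1 + 1L
  h1 <- c2 + n2 + 1L
  p4 <- h1 + n3 + 1L
  if (p4 > length(chars)) return(NULL)
  if (chars[c1] == "C" && chars[c2] == "C" && chars[h1] == "H" &&
      chars[p4] == last)
    c(c1, c2, h1, p4)
  else NULL
}

#' Locate the next WRKY zinc finger
#'
#' Scans from `search_from` for the left-most quadruple of coordinating
#' residues (C, C, H, H or C) whose spacings fall inside `pattern_space`.
#' When both finger types admit a quadruple starting at the same cysteine,
#' C2H2 wins; within a type, smaller spacers are tried first so the
#' left-most-start, most-compact finger is reported.
#'
#' @param sequence Amino-acid string.
#' @param search_from 1-based position at which the search starts.
#' @param pattern_space A [wrky_pattern_space()] object.
#' @return A list with `positions` (the four coordinating residue positions),
#'   `finger_type` (`"C2H2"` or `"C2HC"`) and `spacings` (n1, n2, n3), or
#'   `NULL` when no finger is found.
#' @export
find_zinc_finger <- function(sequence, search_from = 1,
                             pattern_space = wrky_pattern_space()) {
  check_protein_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (search_from < 1 || search_from > length(chars))
    stop_format("search_from outside sequence")
  for (c1 in seq(search_from, length(chars))) {
    if (chars[c1] != "C") next
    for (type in c("C2H2", "C2HC")) {
      sl <- pattern_space[[type]]
      last <- if (type == "C2H2") "H" else "C"
      for (n1 in sort(sl$n1)) for (n2 in sort(sl$n2)) for (n3 in sort(sl$n3)) {
        pos <- match_finger_at(chars, c1, n1, n2, n3, last)
        if (!is.null(pos))
          return(list(positions = pos, finger_type = type,
                      spacings = c(n1, n2, n3)))
      }
    }
  }
  NULL
}

#' Assemble complete WRKY domains
#'
#' Pairs each heptapeptide anchor with the nearest downstream zinc finger
#' whose first cysteine lies within `max_gap` residues of the heptapeptide
#' end. Assembly is greedy left-to-right and a finger is consumed by at most
#' one heptapeptide; anchors without a reachable finger are dropped. When a
#' protein carries two or more domains they are tagged `N`, `C` (and `M` for
#' any middle domains) by order; a lone domain is tagged `only`.
#'
#' @inheritParams find_heptapeptides
#' @param pattern_space A [wrky_pattern_space()] object.
#' @return List of domains; each is a list with `hept_start`, `variant`,
#'   `finger` (as returned by [find_zinc_finger()]), `terminus` and
#'   `signature` (see [spacing_signature()]).
#' @export
assemble_domains <- function(sequence, variant_set = wrky_variants(),
                             pattern_space = wrky_pattern_space()) {
  hepts <- find_heptapeptides(sequence, variant_set)
  domains <- list()
  min_next <- 1L
  for (i in seq_len(nrow(hepts))) {
    h_start <- hepts$start[i]
    h_end <- h_start + 6L
    from <- max(h_end + 1L, min_next)
    if (from > nchar(sequence)) break
    fg <- find_zinc_finger(sequence, from, pattern_space)
    if (is.null(fg)) next
    if (fg$positions[1] - h_end > pattern_space$max_gap) next
    d <- list(hept_start = h_start, variant = hepts$variant[i], finger = fg,
              terminus = "only")
    d$signature <- spacing_signature(d)
    domains[[length(domains) + 1L]] <- d
    min_next <- fg$positions[4] + 1L
  }
  n <- length(domains)
  if (n >= 2) {
    tags <- c("N", rep("M", max(0, n - 2)), "C")
    for (i in seq_len(n)) domains[[i]]$terminus <- tags[i]
  }
  domains
}

#' Render a domain's canonical spacing signature
#'
#' @param domain A domain as returned by [assemble_domains()], or any list
#'   with `finger$spacings` and `finger$finger_type`.
#' @return A string such as `"C-X7-C-X23-H-X1-C"`.
#' @export
spacing_signature <- function(domain) {
  s <- domain$finger$spacings
  last <- if (domain$finger$finger_type == "C2H2") "H" else "C"
  sprintf("C-X%d-C-X%d-H-X%d-%s", s[1], s[2], s[3], last)
}

parse_one_signature <- function(text) {
  t <- gsub("_", "", trimws(text))        # printed dialect uses C-X_5_- style
  m <- regmatches(t, regexec("^C-X(\\d+)-C-X(\\d+)-(.+)$", t))[[1]]
  if (length(m) == 0)
    stop_format("cannot parse zinc-finger signature: '", text, "'")
  n1 <- as.integer(m[2]); n2 <- as.integer(m[3]); tail <- m[4]
  # canonical tail: H-X<n3>-H / H-X<n3>-C
  mt <- regmatches(tail, regexec("^H-X(\\d+)-([HC])$", tail))[[1]]
  if (length(mt)) {
    n3 <- as.integer(mt[2]); last <- mt[3]
  } else {
    # compact printed tail: HXH, HXC, or a literal residue as the one spacer
    # position (e.g. HTC)
    mt <- regmatches(tail, regexec("^H([A-Z])([HC])$", tail))[[1]]
    if (!length(mt))
      stop_format("cannot parse zinc-finger signature tail: '", text, "'")
    n3 <- 1L; last <- mt[3]
  }
  list(finger_type = if (last == "C") "C2HC" else "C2H2",
       spacings = c(n1, n2, n3))
}

#' Parse a zinc-finger spacing signature
#'
#' Accepts the canonical form (`"C-X7-C-X23-H-X1-C"`), the printed dialect
#' with underscores (`"C-X_7_-C-X_23_-HXC"`, where `HXH`/`HTC` style tails
#' stand for a single spacer position, literal residues included), and dual
#' N/C-terminal patterns (`"... (N)/... (C)"`), which yield one parse per
#' domain.
#'
#' @param text Signature string.
#' @return A list of parses; each has `finger_type`, `spacings` and
#'   `terminus` (`"N"`, `"C"` or `"only"`).
#' @examples
#' parse_signature("C-X_7_-C-X_23_-HTC")
#' parse_signature("C-X_4_-C-X_22_-HXH (N)/C-X_4_-C-X_23_-HXH (C)")
#' @export
parse_signature <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(text, "/", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    p <- trimws(p)
    tag <- "only"
    mt <- regmatches(p, regexec("\\(([NC])\\)$", p))[[1]]
    if (length(mt)) {
      tag <- mt[2]
      p <- trimws(sub("\\(([NC])\\)$", "", p))
    }
    parsed <- parse_one_signature(p)
    parsed$terminus <- tag
    out[[length(out) + 1L]] <- parsed
  }
  if (length(out) > 1 && all(vapply(out, `[[`, "", "terminus") == "only"))
    stop_format("dual pattern without (N)/(C) tags: '", text, "'")
  out
}

#' Scan a set of proteins for WRKY domains
#'
#' Convenience wrapper running [assemble_domains()] over a record set.
#'
#' @param records Data frame from [read_fasta()].
#' @inheritParams assemble_domains
#' @return Data frame with one row per detected domain: `id`, `start`,
#'   `variant`, `signature`, `terminus`.
#' @export
scan_domains <- function(records, variant_set = wrky_variants(),
                         pattern_space = wrky_pattern_space()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ds <- assemble_domains(records$sequence[i], variant_set, pattern_space)
    if (!length(ds)) return(NULL)
    data.frame(id = records$id[i],
               start = vapply(ds, `[[`, 0, "hept_start"),
               variant = vapply(ds, `[[`, "", "variant"),
               signature = vapply(ds, `[[`, "", "signature"),
               terminus = vapply(ds, `[[`, "", "terminus"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), start = integer(), variant = character(),
                      signature = character(), terminus = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
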