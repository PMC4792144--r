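# Group and subgroup classification. Groups I/II/III follow directly from
# domain architecture: two C2H2-finger domains -> I; one C2H2 domain -> II;
# one C2HC domain -> III. Subgroups IIa-IIe are not decidable from the
# domain pattern alone and are assigned by phylogenetic placement against a
# labeled reference set (nearest labeled leaf by patristic distance on a
# neighbor-joining tree of the domain sequences).

#' Rule-based group call from domain architecture
#'
#' @param domains List of domains from [assemble_domains()].
#' @return List with `group` (`"I"`, `"II"`, `"III"` or `"unclassified"`) and
#'   `conflict` (TRUE when two or more domains include a C2HC finger, an
#'   architecture outside the canonical rules).
#' @export
classify_by_rule <- function(domains) {
  n <- length(domains)
  if (n == 0) return(list(group = "unclassified", conflict = FALSE))
  types <- vapply(domains, function(d) d$finger$finger_type, "")
  if (n >= 2) {
    return(list(group = "I", conflict = any(types == "C2HC")))
  }
  if (types[1] == "C2H2") list(group = "II", conflict = FALSE)
  else list(group = "III", conflict = FALSE)
}

#' Assign a group II subgroup by tree placement
#'
#' Places the query on a tree (or distance matrix) together with labeled
#' reference domains and returns the label of the nearest reference by
#' patristic distance. Exact ties are resolved by majority vote among the
#' three nearest references, then by the lexicographically smallest label.
#'
#' @param tree_or_distances An [ape::phylo] tree containing the query and all
#'   references as leaves, or a symmetric distance matrix over them.
#' @param query_id Leaf name of the query.
#' @param reference_set Data frame with columns `id` and `label` (labels from
#'   I, IIa-IIe, III); at least one labeled reference must be present.
#' @return The winning label (character scalar).
#' @export
assign_subgroup <- function(tree_or_distances, query_id, reference_set) {
  if (nrow(reference_set) == 0) stop_config("reference set is empty")
  d <- if (inherits(tree_or_distances, "phylo"))
    ape::cophenetic.phylo(tree_or_distances)
  else tree_or_distances
  refs <- intersect(reference_set$id, rownames(d))
  if (!length(refs)) stop_config("no reference present in the tree/distances")
  if (!query_id %in% rownames(d)) stop_config("query '", query_id, "' absent")
  dq <- d[query_id, refs]
  labels <- reference_set$label[match(refs, reference_set$id)]
  nearest <- which(dq == min(dq))
  if (length(nearest) == 1) return(labels[nearest])
  # tie: majority among the 3 nearest, then lexicographic
  o <- order(dq, labels)
  top <- labels[o][seq_len(min(3, length(o)))]
  tab <- sort(table(top), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1]]
  sort(winners)[1]
}

# extract per-protein domain region sequences for tree placement; group I
# contributes its C-terminal domain
placement_sequence <- function(sequence, domains, which_dom = NULL) {
  d <- if (!is.null(which_dom)) domains[[which_dom]] else domains[[length(domains)]]
  substr(sequence, d$hept_start, d$finger$positions[4])
}

#' Classify a protein set into WRKY groups and subgroups
#'
#' Runs [assemble_domains()] and [classify_by_rule()] on every record, then
#' places all single-domain proteins (rule groups II and III) on a
#' neighbor-joining tree together with the labeled reference domains and
#' assigns the nearest reference label. A group II protein whose nearest
#' reference is not a II subgroup, and a group III protein whose nearest
#' reference is not III, are flagged as rule-versus-phylogeny conflicts
#' (never silently overridden). Group I proteins are placed with their
#' C-terminal domain only and receive no subgroup.
#'
#' With `bootstrap > 0`, the placement is repeated on column-resampled
#' alignments and `support` reports the fraction of replicates that
#' reproduce the original label assignment.
#'
#' @param records Data frame from [read_fasta()].
#' @param reference_set Data frame with columns `id`, `label`, `sequence`
#'   (labeled domain sequences, labels from I, IIa-IIe, III).
#' @param pattern_space A [wrky_pattern_space()].
#' @param variant_set Heptapeptide variants, see [wrky_variants()].
#' @param bootstrap Number of bootstrap replicates for assignment support
#'   (0 disables; support is then `NA`).
#' @param seed RNG seed for the bootstrap.
#' @return A `family_table` data frame with one row per input protein:
#'   `gene_id`, `length`, `n_domains`, `group`, `subgroup`, `conflict`,
#'   `support`, `variant`, `signature`.
#' @export
classify_family <- function(records, reference_set,
                            pattern_space = wrky_pattern_space(),
                            variant_set = wrky_variants(),
                            bootstrap = 0, seed = 1) {
  n <- nrow(records)
  tbl <- data.frame(gene_id = records$id,
                    length = nchar(records$sequence),
                    n_domains = rep(0L, n), group = rep("unclassified", n),
                    subgroup = rep(NA_character_, n),
                    conflict = rep(FALSE, n), support = rep(NA_real_, n),
                    variant = rep(NA_character_, n),
                    signature = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(structure(tbl, class = c("family_table", "data.frame")))
  domlist <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- assemble_domains(records$sequence[i], variant_set, pattern_space)
    domlist[[i]] <- ds
    rc <- classify_by_rule(ds)
    tbl$n_domains[i] <- length(ds)
    tbl$group[i] <- rc$group
    tbl$conflict[i] <- rc$conflict
    if (length(ds)) {
      tbl$variant[i] <- ds[[1]]$variant
      tbl$signature[i] <- paste(vapply(ds, `[[`, "", "signature"),
                                collapse = "/")
    }
  }
  place_idx <- which(tbl$group %in% c("II", "III"))
  if (length(place_idx) && nrow(reference_set) > 0) {
    qseqs <- vapply(place_idx, function(i)
      placement_sequence(records$sequence[i], domlist[[i]]), "")
    names(qseqs) <- tbl$gene_id[place_idx]
    seqs <- c(qseqs, setNames(reference_set$sequence, reference_set$id))
    anchor <- reference_set$id[which.max(nchar(reference_set$sequence))]
    msa <- center_star_msa(seqs, anchor)
    d <- pdistance_matrix(msa)
    tree <- neighbor_joining(d)
    labels0 <- character(length(place_idx))
    for (k in seq_along(place_idx)) {
      i <- place_idx[k]
      lab <- assign_subgroup(tree, tbl$gene_id[i], reference_set)
      labels0[k] <- lab
      if (tbl$group[i] == "II") {
        if (lab %in% c("IIa", "IIb", "IIc", "IId", "IIe")) {
          tbl$subgroup[i] <- lab
        } else {
          tbl$conflict[i] <- TRUE
        }
      } else {                       # group III placement check
        if (lab != "III") {
          tbl$conflict[i] <- TRUE
          if (lab %in% c("IIa", "IIb", "IIc", "IId", "IIe"))
            tbl$subgroup[i] <- lab
        }
      }
    }
    if (bootstrap > 0) {
      chars <- do.call(rbind, strsplit(msa, ""))
      rownames(chars) <- names(msa)
      hits <- setNames(numeric(length(place_idx)), tbl$gene_id[place_idx])
      with_seed(seed, {
        for (b in seq_len(bootstrap)) {
          idx <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
          db <- pdistance_boot(chars[, idx, drop = FALSE], rownames(chars))
          tb <- neighbor_joining(db)
          for (k in seq_along(place_idx)) {
            lab <- assign_subgroup(tb, tbl$gene_id[place_idx[k]], reference_set)
            if (identical(lab, labels0[k])) hits[k] <- hits[k] + 1
          }
        }
      })
      tbl$support[place_idx] <- hits / bootstrap
    }
  }
  structure(tbl, class = c("family_table", "data.frame"))
}

main_group <- function(g) {
  ifelse(grepl("^II[a-e]$", g), "II", g)
}

#' Summarize a WRKY family table
#'
#' Works both on the output of [classify_family()] and on the packaged
#' family-table fixture ([load_table1()]); columns are matched by name
#' (`group`, `variant`/`conserved_motif`, `length`/`orf_len_aa`). Group II
#' counts sum the IIa-IIe subgroups.
#'
#' @param tbl A family table.
#' @return List with `n`, `group_counts`, `subgroup_counts`,
#'   `variant_counts`, `length_min`, `length_max`, `length_mean` (rounded to
#'   1 decimal) and `length_mean_raw`.
#' @export
summarize_family <- function(tbl) {
  variant <- tbl$variant %||% tbl$conserved_motif
  len <- tbl$length %||% tbl$orf_len_aa
  grp <- if (!is.null(tbl$subgroup)) {
    ifelse(!is.na(tbl$subgroup), tbl$subgroup, tbl$group)
  } else tbl$group
  mg <- main_group(grp)
  group_counts <- vapply(c("I", "II", "III", "unclassified"),
                         function(g) sum(mg == g, na.rm = TRUE), 0)
  sub_counts <- vapply(c("IIa", "IIb", "IIc", "IId", "IIe"),
                       function(g) sum(grp == g, na.rm = TRUE), 0)
  vtab <- table(variant[!is.na(variant)])
  list(n = nrow(tbl),
       group_counts = group_counts,
       subgroup_counts = sub_counts,
       variant_counts = setNames(as.numeric(vtab), names(vtab)),
       length_min = min(len), length_max = max(len),
       length_mean = round(mean(len), 1),
       length_mean_raw = mean(len))
}
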