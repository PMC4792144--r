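# Seeded generators for every input the pipeline consumes, each returning
# its ground truth alongside the data. Backgrounds are uniform over the
# 20-letter alphabet unless noted; positions inside an implanted WRKY domain
# that are not part of the conserved architecture (linkers and zinc-finger
# spacers) are drawn from an alphabet without C and H so that the implanted
# coordinating residues are the only ones the scanner can see, making
# recovery exact by construction.

SAFE_AA <- setdiff(AA20, c("C", "H"))

rand_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# build one WRKY domain string with a conserved-position mask
build_domain <- function(variant, finger_type, spacings, linker_len = 8) {
  n1 <- spacings[1]; n2 <- spacings[2]; n3 <- spacings[3]
  last <- if (finger_type == "C2H2") "H" else "C"
  pieces <- c(variant,
              rand_aa(linker_len, SAFE_AA),
              "C", rand_aa(n1, SAFE_AA),
              "C", rand_aa(n2, SAFE_AA),
              "H", rand_aa(n3, SAFE_AA),
              last)
  seqchars <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  conserved <- rep(FALSE, length(seqchars))
  conserved[1:7] <- TRUE
  c1 <- 7 + linker_len + 1
  conserved[c(c1, c1 + n1 + 1, c1 + n1 + n2 + 2, c1 + n1 + n2 + n3 + 3)] <- TRUE
  list(seq = paste(seqchars, collapse = ""), conserved = conserved,
       variant = variant, finger_type = finger_type, spacings = spacings)
}

mutate_domain <- function(tmpl, mut_prob) {
  chars <- strsplit(tmpl$seq, "")[[1]]
  mutable <- which(!tmpl$conserved)
  hit <- mutable[runif(length(mutable)) < mut_prob]
  for (i in hit) chars[i] <- sample(setdiff(SAFE_AA, chars[i]), 1)
  paste(chars, collapse = "")
}

default_spacings <- function(group, subgroup = NA) {
  switch(group,
         I = list(N = c(4, 22, 1), C = c(4, 23, 1), type = "C2H2"),
         II = list(only = if (!is.na(subgroup) && subgroup %in% c("IIc"))
                     c(4, 23, 1) else c(5, 23, 1), type = "C2H2"),
         III = list(only = c(7, 23, 1), type = "C2HC"),
         stop_config("unknown group '", group, "'"))
}

#' Generate one synthetic WRKY protein with ground truth
#'
#' Implants one complete WRKY domain (two for group I) into a random
#' background protein. When `subgroup_template` (an element of the
#' `templates` attribute of [gen_reference_set()]) is given, the implanted
#' domain is that template with substitutions applied to non-conserved
#' positions at rate `mut_prob`; the heptapeptide and the four coordinating
#' residues are never mutated.
#'
#' @param group `"I"`, `"II"` or `"III"`.
#' @param subgroup_template Optional domain template for subgroup-faithful
#'   generation.
#' @param spacing_choice Optional numeric vector (n1, n2, n3) overriding the
#'   group-typical finger spacings (single-domain groups only).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param mut_prob Per-site substitution probability on mutable domain
#'   positions (default 0).
#' @param variant Heptapeptide to implant (default `"WRKYGQK"`).
#' @return List with `record` (data frame row: `id`, `species`, `sequence`)
#'   and `truth` (group, subgroup, per-domain heptapeptide start, finger
#'   positions, spacings, finger types).
#' @export
gen_wrky_protein <- function(group, subgroup_template = NULL,
                             spacing_choice = NULL, seed = 1,
                             mut_prob = 0, variant = "WRKYGQK") {
  with_seed(seed, {
    sp <- default_spacings(group, subgroup_template$label %||% NA)
    doms <- list()
    if (group == "I") {
      doms$N <- build_domain(variant, sp$type, sp$N)
      doms$C <- build_domain(variant, sp$type, sp$C)
    } else if (!is.null(subgroup_template)) {
      doms$only <- subgroup_template
    } else {
      doms$only <- build_domain(variant, sp$type, spacing_choice %||% sp$only)
    }
    flank_n <- rand_aa(sample(20:50, 1))
    flank_c <- rand_aa(sample(20:50, 1))
    segs <- character(); truth_dom <- list(); pos <- nchar(flank_n)
    segs <- flank_n
    for (k in seq_along(doms)) {
      if (k > 1) {
        mid <- rand_aa(sample(40:80, 1), SAFE_AA)
        segs <- c(segs, mid); pos <- pos + nchar(mid)
      }
      dseq <- if (mut_prob > 0) mutate_domain(doms[[k]], mut_prob)
      else doms[[k]]$seq
      hept_start <- pos + 1L
      s <- doms[[k]]$spacings
      c1 <- hept_start + 7L + 8L          # heptapeptide + linker
      truth_dom[[k]] <- list(hept_start = hept_start,
                             finger_type = doms[[k]]$finger_type,
                             spacings = s,
                             finger_positions = c(c1, c1 + s[1] + 1,
                                                  c1 + s[1] + s[2] + 2,
                                                  c1 + s[1] + s[2] + s[3] + 3))
      segs <- c(segs, dseq); pos <- pos + nchar(dseq)
    }
    segs <- c(segs, flank_c)
    sequence <- paste(segs, collapse = "")
    list(record = data.frame(id = sprintf("syn_%s_%d", group, seed),
                             species = "Syn", sequence = sequence,
                             stringsAsFactors = FALSE),
         truth = list(group = group,
                      subgroup = subgroup_template$label %||% NA_character_,
                      domains = truth_dom, seed = seed))
  })
}

#' Synthetic labeled reference domain set
#'
#' Builds one labeled WRKY domain template per classification label
#' (I, IIa-IIe, III) with label-typical finger spacings; the non-conserved
#' linker and spacer residues are random per label and provide the
#' discriminative signal for tree placement. This is a synthetic stand-in
#' for a curated reference set (such as labeled Arabidopsis WRKY domains),
#' which users supply for real analyses.
#'
#' @param seed Integer seed.
#' @return Data frame with `id`, `label`, `sequence`; the full template
#'   objects (with conserved-position masks) are attached as attribute
#'   `"templates"`, a list keyed by label.
#' @export
gen_reference_set <- function(seed = 101) {
  specs <- list(I = list("C2H2", c(4, 23, 1)),
                IIa = list("C2H2", c(5, 23, 1)),
                IIb = list("C2H2", c(5, 23, 1)),
                IIc = list("C2H2", c(4, 23, 1)),
                IId = list("C2H2", c(5, 23, 1)),
                IIe = list("C2H2", c(5, 23, 1)),
                III = list("C2HC", c(7, 23, 1)))
  with_seed(seed, {
    templates <- list()
    for (lab in names(specs)) {
      t <- build_domain("WRKYGQK", specs[[lab]][[1]], specs[[lab]][[2]])
      t$label <- lab
      templates[[lab]] <- t
    }
    df <- data.frame(id = paste0("ref_", names(templates)),
                     label = names(templates),
                     sequence = vapply(templates, `[[`, "", "seq"),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    attr(df, "templates") <- templates
    df
  })
}

#' Generate a cohort of synthetic WRKY proteins
#'
#' @param n_per_group Number of proteins per entry of `groups`.
#' @param groups Character vector of group (or subgroup) labels; subgroup
#'   labels use the matching template from `reference_set`.
#' @param seed Integer seed.
#' @param mut_prob Substitution rate on mutable domain positions.
#' @param reference_set A [gen_reference_set()] result (needed for subgroup
#'   labels).
#' @return List with `records` (data frame) and `truth` (data frame `id`,
#'   `group`, `subgroup`).
#' @export
gen_wrky_cohort <- function(n_per_group, groups = c("I", "II", "III"),
                            seed = 1, mut_prob = 0, reference_set = NULL) {
  templates <- if (!is.null(reference_set)) attr(reference_set, "templates")
  recs <- list(); truth <- list(); k <- 0L
  for (g in groups) for (i in seq_len(n_per_group)) {
    k <- k + 1L
    sub <- if (grepl("^II[a-e]$", g)) g else NA_character_
    tmpl <- if (!is.na(sub)) {
      if (is.null(templates)) stop_config("subgroup labels need a reference_set")
      templates[[sub]]
    } else if (g == "III" && !is.null(templates)) {
      # seed group III queries from the labeled III template so that tree
      # placement reflects real affinity rather than random background
      templates[["III"]]
    }
    one <- gen_wrky_protein(if (!is.na(sub)) "II" else g,
                            subgroup_template = tmpl,
                            seed = child_seed(seed, k), mut_prob = mut_prob)
    one$record$id <- sprintf("syn%03d_%s", k, g)
    recs[[k]] <- one$record
    truth[[k]] <- data.frame(id = one$record$id,
                             group = if (!is.na(sub)) "II" else g,
                             subgroup = sub, stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

mutate_seq <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Simulate a gene family along a species tree
#'
#' Ancestral genes evolve along a species tree under a birth (duplication)
#' and death (loss) process with per-site substitution. Each extant pair of
#' genes descending from the same ancestral gene is typed from the recorded
#' event history: the pair's divergence event is either a speciation or a
#' duplication. Same-species pairs are paralogs; cross-species pairs whose
#' divergence is a speciation with no later duplication on either lineage
#' are orthologs; all other cross-species pairs (those descending through a
#' duplication) are coorthologs.
#'
#' @param species_tree An [ape::phylo] tree or a Newick string; default a
#'   three-species tree `((A:1,B:1):1,C:2);`.
#' @param n_genes Number of independent ancestral genes at the root.
#' @param birth_rate Expected duplications per gene per unit branch length.
#' @param loss_rate Loss probability per gene per unit branch length.
#' @param sub_prob Per-site substitution probability per unit branch length.
#' @param seed Integer seed.
#' @param seq_length Ancestral protein length.
#' @return List with `records` (id, species, sequence), `species_map`
#'   (named vector), and `truth_pairs` (data frame `a`, `b`, `type`).
#' @export
simulate_family_evolution <- function(species_tree = "((A:1,B:1):1,C:2);",
                                      n_genes = 10, birth_rate = 0.02,
                                      loss_rate = 0.02, sub_prob = 0.03,
                                      seed = 1, seq_length = 150) {
  tree <- if (inherits(species_tree, "phylo")) species_tree
  else ape::read.tree(text = species_tree)
  with_seed(seed, {
    dup_uid <- 0L
    evolve_branch <- function(genes, len) {
      out <- list()
      for (g in genes) {
        if (runif(1) < min(1, loss_rate * len)) next
        ndup <- rpois(1, birth_rate * len)
        copies <- list(g)
        for (d in seq_len(ndup)) {
          dup_uid <<- dup_uid + 1L
          src <- sample(length(copies), 1)
          base <- copies[[src]]
          copies[[src]]$path <- c(base$path, paste0("D", dup_uid, ".1"))
          copies[[length(copies) + 1L]] <-
            list(seq = base$seq, path = c(base$path, paste0("D", dup_uid, ".2")))
        }
        for (cp in copies) {
          cp$seq <- mutate_seq(cp$seq, min(1, sub_prob * len))
          out[[length(out) + 1L]] <- cp
        }
      }
      out
    }
    n_tips <- length(tree$tip.label)
    root <- n_tips + 1L
    genes_at <- list()
    genes_at[[root]] <- lapply(seq_len(n_genes), function(k)
      list(seq = rand_aa(seq_length), path = paste0("G", k)))
    tips <- list()
    recurse <- function(node) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      for (ci in seq_along(kids)) {
        child <- kids[ci]
        len <- tree$edge.length[which(tree$edge[, 1] == node &
                                        tree$edge[, 2] == child)]
        passed <- lapply(genes_at[[node]], function(g) {
          g$path <- c(g$path, paste0("S", node, ".", ci)); g
        })
        genes_at[[child]] <<- evolve_branch(passed, len)
        if (child <= n_tips) {
          tips[[tree$tip.label[child]]] <<- genes_at[[child]]
        } else {
          recurse(child)
        }
      }
    }
    recurse(root)
    rows <- list(); paths <- list()
    for (sp in names(tips)) {
      gl <- tips[[sp]]
      for (i in seq_along(gl)) {
        id <- sprintf("%s_g%02d", sp, i)
        rows[[id]] <- data.frame(id = id, species = sp, sequence = gl[[i]]$seq,
                                 stringsAsFactors = FALSE)
        paths[[id]] <- gl[[i]]$path
      }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    species_map <- setNames(records$species, records$id)
    truth <- list()
    ids <- records$id
    if (length(ids) >= 2) {
      for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
        p1 <- paths[[ids[i]]]; p2 <- paths[[ids[j]]]
        if (p1[1] != p2[1]) next               # different ancestral genes
        L <- 0L
        while (L < min(length(p1), length(p2)) && p1[L + 1] == p2[L + 1]) L <- L + 1L
        ev1 <- p1[L + 1]                        # divergence tokens share an event id
        same_sp <- species_map[[ids[i]]] == species_map[[ids[j]]]
        type <- if (same_sp) "paralog"
        else if (startsWith(ev1, "D")) "coortholog"
        else if (any(startsWith(c(p1[-seq_len(L + 1)], p2[-seq_len(L + 1)]), "D")))
          "coortholog"
        else "ortholog"
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        truth[[length(truth) + 1L]] <- data.frame(a = a, b = b, type = type,
                                                  stringsAsFactors = FALSE)
      }
    }
    truth_pairs <- do.call(rbind, truth) %||%
      data.frame(a = character(), b = character(), type = character(),
                 stringsAsFactors = FALSE)
    list(records = records, species_map = species_map,
         truth_pairs = truth_pairs, seed = seed)
  })
}

#' Generate gene models with planted intron counts
#'
#' @param intron_count_spec Integer vector of intron counts, one per gene to
#'   generate (e.g. `c(0, 2, 2, 3)`), or a named histogram
#'   (`c("0" = 8, "2" = 42)`).
#' @param seed Integer seed.
#' @return List with `models` (list of [gene_model()]) and `truth` (integer
#'   vector of planted intron counts, named by gene id).
#' @export
gen_gene_models <- function(intron_count_spec, seed = 1) {
  if (!is.null(names(intron_count_spec)))
    intron_count_spec <- rep(as.integer(names(intron_count_spec)),
                             times = intron_count_spec)
  with_seed(seed, {
    models <- list()
    for (i in seq_along(intron_count_spec)) {
      nex <- intron_count_spec[i] + 1L
      id <- sprintf("gene%03d", i)
      pos <- sample(1:100000, 1)
      starts <- integer(nex); ends <- integer(nex)
      for (e in seq_len(nex)) {
        starts[e] <- pos
        ends[e] <- pos + sample(50:300, 1)
        pos <- ends[e] + sample(50:500, 1)   # next intron
      }
      models[[id]] <- gene_model(id, sample(c("+", "-"), 1),
                                 cbind(starts, ends))
    }
    list(models = models,
         truth = setNames(as.integer(intron_count_spec), names(models)))
  })
}

# destroy any dictionary match in a background sequence by mutating one base
# inside each matched window; iterate until clean
clean_background <- function(bg, dictionary, max_rounds = 50) {
  for (r in seq_len(max_rounds)) {
    hits <- scan_cis_elements(bg, dictionary)
    if (!nrow(hits)) return(bg)
    chars <- strsplit(bg, "")[[1]]
    for (k in seq_len(nrow(hits))) {
      w <- nchar(hits$match[k])
      p <- hits$start[k] + sample(w, 1) - 1L
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    bg <- paste(chars, collapse = "")
  }
  stop_format("could not generate an element-free background")
}

instantiate_consensus <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(ch)
    sample(strsplit(IUPAC_DNA[[ch]], "")[[1]], 1), ""), collapse = "")
}

#' Generate promoters with implanted cis-elements
#'
#' Backgrounds are uniform over A, C, G, T, then scrubbed of accidental
#' dictionary matches; the requested elements are implanted at
#' non-overlapping random positions, each on a random strand. Promoters are
#' re-drawn if an implant's boundary accidentally creates an extra match, so
#' the recorded truth is the complete hit list.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp (default 1500, the conventional
#'   upstream window).
#' @param implant_spec Character vector of element names implanted in every
#'   promoter, or a list of such vectors (one per promoter).
#' @param seed Integer seed.
#' @param dictionary Element dictionary (default
#'   [cis_element_dictionary()]).
#' @return List with `promoters` (named character vector) and `truth`
#'   (data frame `promoter`, `element`, `start`, `strand`, `match`).
#' @export
gen_promoters <- function(n, length = 1500, implant_spec = c("W-box", "ABRE"),
                          seed = 1, dictionary = cis_element_dictionary()) {
  if (!is.list(implant_spec)) implant_spec <- rep(list(implant_spec), n)
  stopifnot(length(implant_spec) == n)
  with_seed(seed, {
    proms <- setNames(character(n), sprintf("prom%03d", seq_len(n)))
    truth <- list()
    for (i in seq_len(n)) {
      elems <- implant_spec[[i]]
      for (attempt in 1:20) {
        bg <- clean_background(rand_aa(length, c("A", "C", "G", "T")),
                               dictionary)
        chars <- strsplit(bg, "")[[1]]
        placed <- data.frame(element = character(), start = integer(),
                             strand = character(), match = character(),
                             stringsAsFactors = FALSE)
        occupied <- rep(FALSE, length)
        ok <- TRUE
        for (e in elems) {
          cons <- dictionary$consensus[dictionary$name == e]
          if (!length(cons)) stop_config("unknown element '", e, "'")
          w <- nchar(cons)
          site <- instantiate_consensus(cons)
          strand <- sample(c("+", "-"), 1)
          plus_site <- if (strand == "+") site else revcomp(site)
          spot <- NA
          for (try in 1:100) {
            s <- sample(length - w + 1, 1)
            if (!any(occupied[s:(s + w - 1)])) { spot <- s; break }
          }
          if (is.na(spot)) { ok <- FALSE; break }
          chars[spot:(spot + w - 1)] <- strsplit(plus_site, "")[[1]]
          occupied[spot:(spot + w - 1)] <- TRUE
          placed <- rbind(placed, data.frame(element = e, start = spot,
                                             strand = strand,
                                             match = plus_site,
                                             stringsAsFactors = FALSE))
        }
        if (!ok) next
        cand <- paste(chars, collapse = "")
        got <- scan_cis_elements(cand, dictionary)
        expect <- placed[order(placed$start, placed$element), , drop = FALSE]
        # palindromic implants are reported on the plus strand
        pal <- expect$strand == "-" &
          vapply(expect$match, function(m) identical(m, revcomp(m)), TRUE)
        expect$strand[pal] <- "+"
        rownames(expect) <- NULL
        if (isTRUE(all.equal(got[, c("element", "start", "strand", "match")],
                             expect[, c("element", "start", "strand", "match")],
                             check.attributes = FALSE))) {
          proms[i] <- cand
          if (nrow(expect))
            truth[[i]] <- cbind(promoter = names(proms)[i], expect)
          break
        }
      }
      if (!nzchar(proms[i]))
        stop_format("failed to place implants without side effects")
    }
    truth_df <- do.call(rbind, truth) %||%
      data.frame(promoter = character(), element = character(),
                 start = integer(), strand = character(), match = character(),
                 stringsAsFactors = FALSE)
    rownames(truth_df) <- NULL
    list(promoters = proms, truth = truth_df)
  })
}

#' Generate a count matrix with planted co-expression modules
#'
#' Counts are negative binomial around gene base means; genes belonging to a
#' module share a per-sample latent factor with the module's loading, which
#' plants positive (same-sign loadings) or negative (opposite-sign
#' loadings, via a shared `factor` index) correlations.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param modules List of module specs, each
#'   `list(genes = <indices>, loading = <numeric>, factor = <optional
#'   shared factor index>)`.
#' @param nb_dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param seed Integer seed.
#' @return List with `em` (an [expression_matrix()]) and `truth`
#'   (module membership data frame and the latent factors).
#' @export
gen_expression <- function(n_genes = 100, n_samples = 8,
                           modules = list(list(genes = 1:10, loading = 0.9)),
                           nb_dispersion = 0.2, seed = 1) {
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    sample_ids <- sprintf("s%02d", seq_len(n_samples))
    base <- exp(rnorm(n_genes, log(200), 0.4))
    loading <- rep(0, n_genes)
    factor_of <- rep(NA_integer_, n_genes)
    n_factors <- 0L
    for (m in modules) {
      fid <- m$factor %||% (n_factors + 1L)
      n_factors <- max(n_factors, fid)
      loading[m$genes] <- m$loading
      factor_of[m$genes] <- fid
    }
    f <- matrix(rnorm(n_factors * n_samples), n_factors, n_samples)
    mu <- matrix(base, n_genes, n_samples)
    for (i in which(!is.na(factor_of)))
      mu[i, ] <- base[i] * exp(loading[i] * f[factor_of[i], ])
    counts <- matrix(rnbinom(n_genes * n_samples, mu = mu,
                             size = 1 / nb_dispersion),
                     n_genes, n_samples,
                     dimnames = list(gene_ids, sample_ids))
    lens <- setNames(sample(500:3000, n_genes, replace = TRUE), gene_ids)
    em <- expression_matrix(counts, lens)
    list(em = em,
         truth = list(membership = data.frame(gene = gene_ids,
                                              factor = factor_of,
                                              loading = loading,
                                              stringsAsFactors = FALSE),
                      factors = f))
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Ct values are constructed by inverting the 2^-ddCt model: per gene a
#' calibrator dCt baseline is drawn, and each condition's dCt is the
#' baseline minus `log2(fold)`; reference-gene Ct is around 20. Gaussian
#' noise of `noise_sd` is added independently to target and reference Ct of
#' every replicate, so at `noise_sd = 0` the planted folds are recovered
#' exactly.
#'
#' @param true_folds Data frame `gene`, `condition`, `fold` (the calibrator
#'   condition is added automatically with fold 1 if absent).
#' @param reference_gene Reference gene name recorded in the table
#'   (default `"DcTUB"`).
#' @param calibrator Calibrator condition name (default `"control"`).
#' @param noise_sd Ct noise standard deviation.
#' @param n_reps Technical replicates per reaction (default 3).
#' @param seed Integer seed.
#' @return List with `ct_table` (columns `gene`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference`, `reference_gene`) and `truth`
#'   (the fold table including the calibrator).
#' @export
gen_ct_table <- function(true_folds, reference_gene = "DcTUB",
                         calibrator = "control", noise_sd = 0, n_reps = 3,
                         seed = 1) {
  with_seed(seed, {
    genes <- unique(true_folds$gene)
    add <- genes[!genes %in% true_folds$gene[true_folds$condition == calibrator]]
    if (length(add))
      true_folds <- rbind(true_folds,
                          data.frame(gene = add, condition = calibrator,
                                     fold = 1, stringsAsFactors = FALSE))
    baseline <- setNames(runif(length(genes), 2, 6), genes)
    rows <- list()
    for (k in seq_len(nrow(true_folds))) {
      g <- true_folds$gene[k]; cond <- true_folds$condition[k]
      dct <- baseline[[g]] - log2(true_folds$fold[k])
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene = g, condition = cond, replicate = r,
                     ct_target = 20 + dct + rnorm(1, 0, noise_sd),
                     ct_reference = 20 + rnorm(1, 0, noise_sd),
                     reference_gene = reference_gene,
                     stringsAsFactors = FALSE)
      }
    }
    list(ct_table = do.call(rbind, rows), truth = true_folds)
  })
}
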