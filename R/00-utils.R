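# internal helpers shared across modules

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + k * 7919) %% 2147483647
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("wrky_config_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("wrky_format_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0)
    stop_format(what, " must be a non-empty string")
  bad <- setdiff(strsplit(x, "")[[1]], c(AA20, "X", "*"))
  if (length(bad))
    stop_format(what, " contains non-amino-acid characters: ",
                paste(unique(bad), collapse = ", "))
  invisible(x)
}
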