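#!/usr/bin/env Rscript

# Thin command-line wrapper over the package's experiment runner.
#
#   Rscript scripts/richlazy.R run <config.yaml> [--seed N] [--n-seeds N] [--out DIR]
#   Rscript scripts/richlazy.R summarize <dir>

suppressMessages(library(richlazy))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: richlazy.R run <config.yaml|config.json> [--seed N] [--n-seeds N] [--out DIR]\n",
      "       richlazy.R summarize <dir>\n")
  quit(status = 1)
}
if (length(args) < 2) usage()

cmd <- args[1]
get_arg <- function(flag) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) NULL else args[i + 1]
}

if (cmd == "run") {
  config <- if (grepl("\\.json$", args[2])) {
    jsonlite::read_json(args[2], simplifyVector = TRUE)
  } else {
    yaml::read_yaml(args[2])
  }
  seed <- get_arg("--seed")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  n_seeds <- get_arg("--n-seeds")
  if (!is.null(n_seeds)) config$n_seeds <- as.integer(n_seeds)
  out <- get_arg("--out")
  if (!is.null(out)) config$out_dir <- out
  bundle <- run_experiment(config)
  print(bundle)
} else if (cmd == "summarize") {
  results <- utils::read.csv(file.path(args[2], "results.csv"))
  bundle <- structure(list(results = tibble::as_tibble(results)),
                      class = "result_bundle")
  print(summarize_experiment(bundle))
} else {
  usage()
}
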