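#' Run code with a temporary RNG state
#'
#' Seeds the generator, runs `code`, and restores the previous RNG state so
#' library functions never perturb a caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream seed from a master seed and a label
#'
#' Stable integer hash so that every subject/run/stage gets an independent,
#' reproducible RNG stream from a single master seed. The result is always a
#' valid 32-bit seed.
#'
#' @param master Integer master seed.
#' @param label Character label naming the stream (e.g. "subjA/run2/noise").
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1, is.finite(master), length(label) == 1)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 1e9
  # keep all arithmetic within double precision (< 2^53)
  as.integer((abs(as.numeric(master)) %% 1e9 * 2654435 + h * 40503 + 17) %%
               (2^31 - 1))
}

#' Write a data frame as TSV
#' @param x Data frame or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}

#' Write a provenance sidecar next to an output file
#'
#' Every pipeline output gets a `<file>.json` sidecar recording the stage,
#' parameters, seed and package version, so results can be traced without a
#' database.
#'
#' @param path Path of the data file the sidecar describes.
#' @param stage Stage name.
#' @param params Named list of parameters.
#' @param seed Seed used (or `NA`).
#' @param timestamp Include a wall-clock timestamp. Off by default so that
#'   repeated runs with one seed are byte-identical.
#' @return Sidecar path, invisibly.
#' @export
write_provenance <- function(path, stage, params = list(), seed = NA,
                             timestamp = FALSE) {
  rec <- list(stage = stage, file = basename(path), parameters = params,
              seed = seed,
              package = as.character(utils::packageVersion("dyadfmri")))
  if (timestamp) rec$timestamp <- format(Sys.time(), tz = "UTC")
  side <- paste0(path, ".json")
  jsonlite::write_json(rec, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}
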