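DPC_SCHEMA <- "dpcnet/1"

#' Save a dpcnet object with a versioned schema
#'
#' Persists parameters, datasets, memories or trajectories together with a
#' schema-version string; [load_dpc()] refuses files written under a
#' different schema. Arrays round-trip bit-exactly.
#'
#' @param x Object to save (`dpc_params`, `dpc_dataset`, `dpc_memory`,
#'   `dpc3_params`, trajectories, ...).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_dpc <- function(x, path) {
  if (inherits(x, "dpc_dataset") && n_sequences(x) == 0)
    stop_invalid("refusing to save an empty dataset")
  saveRDS(list(schema = DPC_SCHEMA, class = class(x), payload = x), path)
  invisible(path)
}

#' Load a dpcnet object saved by [save_dpc()]
#'
#' @param path File path.
#' @return The stored object.
#' @export
load_dpc <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema, DPC_SCHEMA))
    stop(structure(class = c("dpc_schema_error", "error", "condition"),
                   list(message = paste0("schema mismatch: expected ",
                                         DPC_SCHEMA, ", found ",
                                         paste(obj$schema, collapse = "/")),
                        call = sys.call(-1))))
  obj$payload
}

## Minimal key: value config parser ('#' comments, blank lines ignored).
## Values are coerced to numeric when possible; comma lists become vectors.
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[:=]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop_invalid("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

write_manifest <- function(out_dir, cmd, cfg, seed, extra = list()) {
  manifest <- c(list(command = cmd, seed = seed,
                     package_version = as.character(utils::packageVersion("dpcnet")),
                     schema = DPC_SCHEMA,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = cfg), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
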