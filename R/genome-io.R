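#' Read / write genomes as JSON
#'
#' Genomes are stored as flat JSON objects keyed by gene name, e.g.
#' `{"n_blocks": 5, "first_filters": 8, ...}`. Three discovered genomes are
#' shipped under `system.file("extdata", "genomes", package = "gaunet")`:
#' `lung.json`, `dsb2018.json` and `liver.json`.
#'
#' @param path File path.
#' @param space Search space the genome is validated against.
#' @return `read_genome()` returns a `ga_genome`; `write_genome()` returns
#'   `path` invisibly.
#' @export
#' @examples
#' f <- system.file("extdata", "genomes", "lung.json", package = "gaunet")
#' read_genome(f)
read_genome <- function(path, space = search_space()) {
  if (!file.exists(path)) stop("no such genome file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed genome JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  missing <- setdiff(GENE_NAMES, names(obj))
  if (length(missing) > 0L) {
    stop("genome file '", path, "' missing gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(genome, c(obj[GENE_NAMES], list(space = space)))
}

#' @rdname read_genome
#' @param g A `ga_genome` to serialize.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "ga_genome"))
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Published discovered genomes
#'
#' Convenience accessor for the three discovered genomes shipped with the
#' package: `"lung"` (5 blocks, 8 filters, 5x5 kernels, ELU, max-pool, Adam,
#' lr 1e-4, batch 8), `"dsb2018"` (5 blocks, 8 filters, 7x7, ReLU, batch
#' norm, Adamax, lr 5e-4, batch 16) and `"liver"` (7 blocks, 8 filters, 4x4,
#' ReLU, batch norm, Adam, lr 1e-4, batch 4).
#'
#' @param name One of `"lung"`, `"dsb2018"`, `"liver"`.
#' @return A `ga_genome`.
#' @export
#' @examples
#' discovered_genome("liver")
discovered_genome <- function(name = c("lung", "dsb2018", "liver")) {
  name <- match.arg(name)
  path <- system.file("extdata", "genomes", paste0(name, ".json"),
                      package = "gaunet", mustWork = TRUE)
  read_genome(path)
}
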