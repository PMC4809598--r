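# Thin TSV/CSV wrappers (data.table) so every output is a plain text
# table with a header and no row names.

write_tsv <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

write_csv <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, quote = FALSE)
  invisible(path)
}

read_csv <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' Write a simulated experiment to a directory
#'
#' Writes \code{counts.tsv} (gene column plus one integer column per
#' sample), \code{gene_lengths.tsv}, \code{samples.tsv},
#' \code{annotation.tsv}, the phenotype tables (\code{weights.csv},
#' \code{intake.csv}, \code{events.csv}, \code{carcass.csv},
#' \code{animals.csv}) and the planted truth as \code{truth.json}.
#'
#' @param sim a [simulate_expression()] result.
#' @param pheno a [simulate_phenotypes()] result (optional).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, pheno = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- sim$counts
  write_tsv(data.frame(gene = rownames(cm$counts), cm$counts,
                       check.names = FALSE),
            file.path(dir, "counts.tsv"))
  write_tsv(data.frame(gene = names(cm$lengths),
                       length = unname(cm$lengths)),
            file.path(dir, "gene_lengths.tsv"))
  write_tsv(sim$meta, file.path(dir, "samples.tsv"))
  write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(
    list(true_ts = as.list(sim$truth$true_ts),
         true_de = as.list(sim$truth$true_de),
         true_hubs = sim$truth$true_hubs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(pheno)) {
    write_csv(pheno$animals, file.path(dir, "animals.csv"))
    write_csv(pheno$weights, file.path(dir, "weights.csv"))
    write_csv(pheno$intake, file.path(dir, "intake.csv"))
    write_csv(pheno$events, file.path(dir, "events.csv"))
    write_csv(pheno$carcass, file.path(dir, "carcass.csv"))
  }
  invisible(dir)
}

#' Read a count experiment from a directory
#'
#' Reads the files written by [write_simulation()] (or equivalently
#' formatted user data): \code{counts.tsv}, \code{gene_lengths.tsv},
#' \code{samples.tsv} and optionally \code{annotation.tsv}.
#'
#' @param dir directory holding the tables.
#' @return list with \code{counts} (a [count_matrix()]), \code{meta} and
#'   \code{annotation} (NULL when absent).
#' @export
read_experiment <- function(dir) {
  cts <- read_tsv(file.path(dir, "counts.tsv"))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene
  len <- read_tsv(file.path(dir, "gene_lengths.tsv"))
  meta <- validate_sample_meta(read_tsv(file.path(dir, "samples.tsv")))
  ann_path <- file.path(dir, "annotation.tsv")
  ann <- if (file.exists(ann_path)) read_tsv(ann_path) else NULL
  list(counts = count_matrix(m, setNames(len$length, len$gene)),
       meta = meta, annotation = ann)
}
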