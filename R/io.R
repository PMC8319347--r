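# Readers and writers for the plain-text formats the pipeline exchanges.

#' Read and write pipeline tables
#'
#' Trajectory tables are TSV (line, organism, generation, gene, frequency,
#' annotation); single-cell matrices are CSV with a `cell` id column and one
#' 0/1/3 column per mutation; plate reads are wide CSV (time + one column
#' per well); pairing tables are CSV (pairing, metric, replicate, value).
#'
#' @param x Object to write.
#' @param path File path.
#' @name syntroph_io
NULL

#' @rdname syntroph_io
#' @export
write_trajectories <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname syntroph_io
#' @export
read_trajectories <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname syntroph_io
#' @export
write_mutation_matrix <- function(x, path) {
  df <- as_tibble(as.data.frame(unclass(x)), rownames = "cell")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname syntroph_io
#' @param fd,ad Error rates to attach on read.
#' @export
read_mutation_matrix <- function(path, fd = 6.04e-5, ad = 0.21545) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  mutation_matrix(m, fd = fd, ad = ad)
}

#' @rdname syntroph_io
#' @export
write_plate <- function(x, path) {
  wide <- pivot_wider(x$curves, names_from = "well", values_from = "od")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname syntroph_io
#' @param map_path Plate-map CSV path (well, density, replicate, blank).
#' @export
read_plate <- function(path, map_path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  curves <- pivot_longer(wide, -"time", names_to = "well", values_to = "od")
  map_df <- readr::read_csv(map_path, show_col_types = FALSE)
  structure(list(curves = curves[, c("well", "time", "od")], map = map_df,
                 truth = NULL),
            class = "plate_assay")
}

#' Write per-caller call sets as minimal VCF files
#'
#' One VCF per caller (`<dir>/<caller>.vcf`), with the consensus-relevant
#' fields: CHROM, POS, REF, ALT and the allele frequency as `INFO AF`.
#'
#' @param calls Tibble of calls with a `caller` column (as produced by
#'   [simulate_caller_outputs()]).
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_caller_vcfs <- function(calls, dir) {
  check_columns(calls, c("caller", "chrom", "position", "ref", "alt",
                         "frequency"), "calls")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- map_chr(split(calls, calls$caller), function(df) {
    path <- file.path(dir, paste0(df$caller[1], ".vcf"))
    header <- c(
      "##fileformat=VCFv4.2",
      sprintf("##source=%s", df$caller[1]),
      '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele Frequency">',
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f",
                    df$chrom, df$position, df$ref, df$alt, df$frequency)
    writeLines(c(header, body), path)
    path
  })
  invisible(paths)
}

#' Read per-caller VCFs back into one call table
#'
#' Uses `vcfR` when available, else a minimal column parser for the VCF
#' subset written by [write_caller_vcfs()].
#'
#' @param paths VCF file paths; caller names default to the file base names.
#' @return Tibble (caller, chrom, position, ref, alt, frequency).
#' @export
read_caller_vcfs <- function(paths) {
  callers <- sub("\\.vcf$", "", basename(paths))
  bind_rows(map2(paths, callers, function(path, caller) {
    if (requireNamespace("vcfR", quietly = TRUE)) {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
      af <- as.numeric(vcfR::extract.info(v, "AF"))
      tibble(caller = caller, chrom = fx$CHROM,
             position = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
             frequency = af)
    } else {
      lines <- readLines(path)
      body <- lines[!startsWith(lines, "#")]
      if (length(body) == 0) {
        return(tibble(caller = character(), chrom = character(),
                      position = integer(), ref = character(),
                      alt = character(), frequency = numeric()))
      }
      parts <- strsplit(body, "\t", fixed = TRUE)
      tibble(
        caller = caller,
        chrom = map_chr(parts, 1),
        position = as.integer(map_chr(parts, 2)),
        ref = map_chr(parts, 4),
        alt = map_chr(parts, 5),
        frequency = as.numeric(sub("^AF=", "", map_chr(parts, 8)))
      )
    }
  }))
}
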