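#' Read the tabular input formats
#'
#' Three tab-separated, headered, UTF-8 files describe an analysis ('.' is
#' the missing-value marker; positions are 1-based inclusive):
#' \describe{
#'   \item{frequency table}{columns `chrom`, `pos`, `anc`, `der`, `x` — one
#'     row per SNP with the modern derived-allele frequency `x`.}
#'   \item{read-count table}{columns `chrom`, `pos`, `ind`, `n_anc`,
#'     `n_der` — one row per SNP x individual with at least one read;
#'     absent pairs mean zero reads.}
#'   \item{panel file}{columns `ind`, `pop` and optionally `age`, `note` —
#'     assignment of individuals to ancient populations.}
#' }
#' `read_freq_table()`, `read_count_table()` and `read_panel()` parse and
#' validate one file each; [read_dataset()] joins them into per-population
#' [continuity_dataset()] objects.
#'
#' @param path File path.
#' @return A `data.table` with the validated columns.
#' @export
read_freq_table <- function(path) {
  ft <- fread_checked(path, c("chrom", "pos", "anc", "der", "x"))
  if (anyDuplicated(ft[, c("chrom", "pos")])) {
    d <- which(duplicated(ft[, c("chrom", "pos")]))[1L]
    stop(sprintf("duplicate (chrom,pos) key in '%s' at data line %d", path, d),
         call. = FALSE)
  }
  if (any(!is.finite(ft$x)) || any(ft$x < 0) || any(ft$x > 1))
    stop(sprintf("frequency column x outside [0, 1] in '%s'", path), call. = FALSE)
  ft
}

#' @rdname read_freq_table
#' @export
read_count_table <- function(path) {
  rt <- fread_checked(path, c("chrom", "pos", "ind", "n_anc", "n_der"))
  bad <- which(rt$n_anc < 0 | rt$n_der < 0 |
               rt$n_anc != round(rt$n_anc) | rt$n_der != round(rt$n_der))
  if (length(bad))
    stop(sprintf("negative or non-integer read count in '%s' at data line %d",
                 path, bad[1L]), call. = FALSE)
  rt
}

#' @rdname read_freq_table
#' @export
read_panel <- function(path) {
  pn <- fread_checked(path, c("ind", "pop"))
  if (anyDuplicated(pn$ind))
    stop(sprintf("duplicate individual ID in panel file '%s'", path), call. = FALSE)
  pn
}

fread_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                          data.table = FALSE)
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  dt
}

#' Read modern frequencies from a VCF
#'
#' Extracts biallelic SNPs and a per-site allele frequency from a standard
#' VCF (uncompressed or bgzipped), yielding the same table as
#' [read_freq_table()]: REF is taken as the ancestral and ALT as the
#' derived allele, and `field` names the INFO key holding the derived
#' (ALT) allele frequency. Multiallelic records and records lacking the
#' field are dropped with a message.
#'
#' @param path VCF path.
#' @param field INFO field with the ALT allele frequency (default `"AF"`).
#' @return A data.frame with columns chrom, pos, anc, der, x.
#' @export
read_freq_vcf <- function(path, field = "AF") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = field)))
  keep <- !grepl(",", fix$ALT, fixed = TRUE) & nchar(fix$REF) == 1L &
          nchar(fix$ALT) == 1L & is.finite(af)
  if (any(!keep))
    message(sprintf("read_freq_vcf: dropped %d multiallelic/indel/missing-%s record(s)",
                    sum(!keep), field))
  out <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                    anc = fix$REF[keep], der = fix$ALT[keep], x = af[keep],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("chrom", "pos")]))
    stop(sprintf("duplicate (chrom,pos) key in VCF '%s'", path), call. = FALSE)
  out
}

#' Assemble per-population datasets from the input tables
#'
#' Joins the frequency, read-count and panel tables on (chrom, pos) and
#' individual ID, applies the site filters (no modern frequency,
#' non-segregating modern frequency, zero reads across the population's
#' panel), and returns one [continuity_dataset()] per population together
#' with full per-reason drop accounting. `sites_in = sites_used +
#' sum(drop counts)` is asserted for every population.
#'
#' @param freq Path to the frequency table, or a data.frame as returned by
#'   [read_freq_table()] / [read_freq_vcf()].
#' @param reads Path to the read-count table, or an equivalent data.frame.
#' @param panel Path to the panel file, or an equivalent data.frame.
#' @param min_single_cov Optional panel filter: populations consisting of a
#'   single individual with mean coverage below this value are excluded
#'   (0 disables; 2 excludes lone individuals below 2x, a common practice).
#' @return List with elements `datasets` (named list of
#'   [continuity_dataset()]), `filters` (per-population drop counts), and
#'   `excluded_pops`.
#' @export
read_dataset <- function(freq, reads, panel, min_single_cov = 0) {
  ft <- if (is.character(freq)) read_freq_table(freq) else as.data.frame(freq)
  rt <- if (is.character(reads)) read_count_table(reads) else as.data.frame(reads)
  pn <- if (is.character(panel)) read_panel(panel) else as.data.frame(panel)

  unknown <- setdiff(unique(rt$ind), pn$ind)
  if (length(unknown))
    stop(sprintf("read-count table names individual(s) absent from the panel: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  key_f <- paste(ft$chrom, ft$pos)
  key_r <- paste(rt$chrom, rt$pos)
  no_freq <- !(key_r %in% key_f)
  n_reads_no_freq <- length(unique(key_r[no_freq]))
  rt <- rt[!no_freq, , drop = FALSE]
  key_r <- key_r[!no_freq]

  datasets <- list(); filters <- list(); excluded <- character(0)
  n_usable_pops <- 0L
  for (pop in unique(pn$pop)) {
    inds <- pn$ind[pn$pop == pop]
    sites_in <- nrow(ft)
    seg <- ft$x > 0 & ft$x < 1
    n_nonseg <- sum(!seg)
    sub <- rt[rt$ind %in% inds, , drop = FALSE]
    anc <- matrix(0, sites_in, length(inds), dimnames = list(NULL, inds))
    der <- matrix(0, sites_in, length(inds))
    colnames(der) <- inds
    row_idx <- match(paste(sub$chrom, sub$pos), key_f)
    col_idx <- match(sub$ind, inds)
    anc[cbind(row_idx, col_idx)] <- sub$n_anc
    der[cbind(row_idx, col_idx)] <- sub$n_der
    covered <- rowSums(anc + der) > 0
    n_nocov <- sum(seg & !covered)
    used <- seg & covered
    stopifnot(sites_in == sum(used) + n_nonseg + n_nocov)  # filter accounting
    filters[[pop]] <- c(sites_in = sites_in, used = sum(used),
                        dropped_nonsegregating = n_nonseg,
                        dropped_no_reads = n_nocov,
                        reads_without_frequency = n_reads_no_freq)
    if (!any(used)) {
      warning(sprintf("population '%s': no usable sites; skipped", pop))
      excluded <- c(excluded, pop)
      next
    }
    n_usable_pops <- n_usable_pops + 1L
    ds <- continuity_dataset(ft$x[used], anc[used, , drop = FALSE],
                             der[used, , drop = FALSE],
                             individuals = inds, population = pop)
    cov <- mean(colSums(ds$anc + ds$der) / n_sites(ds))
    if (length(inds) == 1L && min_single_cov > 0 && cov < min_single_cov) {
      message(sprintf(
        "population '%s' excluded: single individual at %.2fx < %.2fx", pop,
        cov, min_single_cov))
      excluded <- c(excluded, pop)
      next
    }
    datasets[[pop]] <- ds
  }
  if (n_usable_pops == 0L)
    stop("empty intersection of frequency and read-count sites: no population has usable sites",
         call. = FALSE)
  list(datasets = datasets, filters = filters, excluded_pops = excluded)
}

#' Write a simulated dataset in the tabular input formats
#'
#' Emits `<prefix>.freq.tsv`, `<prefix>.reads.tsv`, `<prefix>.panel.tsv`
#' and a provenance sidecar `<prefix>.provenance.json` carrying the full
#' simulation configuration and seed. Sites are placed on a synthetic
#' chromosome `"sim1"` at consecutive 1-based positions with placeholder
#' A/G alleles.
#'
#' @param ds A [continuity_dataset()] (typically from [simulate_dataset()]).
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "continuity_dataset"))
  L <- n_sites(ds); m <- n_individuals(ds)
  freq <- data.frame(chrom = "sim1", pos = seq_len(L), anc = "A", der = "G",
                     x = ds$x)
  depth <- ds$anc + ds$der
  idx <- which(depth > 0, arr.ind = TRUE)
  reads <- data.frame(chrom = "sim1", pos = idx[, 1L],
                      ind = ds$individuals[idx[, 2L]],
                      n_anc = ds$anc[idx], n_der = ds$der[idx])
  reads <- reads[order(reads$pos, reads$ind), , drop = FALSE]
  panel <- data.frame(ind = ds$individuals, pop = ds$population)
  files <- paste0(prefix, c(".freq.tsv", ".reads.tsv", ".panel.tsv",
                            ".provenance.json"))
  data.table::fwrite(freq, files[1L], sep = "\t", na = ".")
  data.table::fwrite(reads, files[2L], sep = "\t", na = ".")
  data.table::fwrite(panel, files[3L], sep = "\t", na = ".")
  prov <- attr(ds, "provenance")
  if (is.null(prov)) prov <- list()
  jsonlite::write_json(prov, files[4L], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(files)
}

#' Summarize fits into the results table
#'
#' One row per population in the conventional continuity-analysis layout: `pop`,
#' `cov` (mean individual coverage), full-model estimates `t1`, `t2`,
#' `eps`, `lnL`, continuity-model estimates `t1_cont`, `lnL_cont`, the LRT
#' statistic and its two p-values, plus a `status` column (`"ok"` or
#' `"failed"`).
#'
#' @param tests Named list (by population) of [continuity_test()] results,
#'   or `NA` for failed populations.
#' @param datasets Named list of the matching [continuity_dataset()]s.
#' @return A data.frame.
#' @export
results_table <- function(tests, datasets) {
  rows <- lapply(names(tests), function(pop) {
    ds <- datasets[[pop]]
    cov <- if (!is.null(ds)) mean(colSums(ds$anc + ds$der) / n_sites(ds)) else NA_real_
    tt <- tests[[pop]]
    if (inherits(tt, "continuity_lrt")) {
      data.frame(pop = pop, cov = cov,
                 t1 = tt$fit_full$t1, t2 = tt$fit_full$t2,
                 eps = mean(tt$fit_full$eps), lnL = tt$lnL_full,
                 t1_cont = if (is.null(tt$fit_null)) NA_real_ else tt$fit_null$t1,
                 lnL_cont = tt$lnL_null,
                 lrt = tt$lrt, p_chi2_1df = tt$p_chi2_1df,
                 p_mixture = tt$p_mixture, status = "ok",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pop = pop, cov = cov, t1 = NA_real_, t2 = NA_real_,
                 eps = NA_real_, lnL = NA_real_, t1_cont = NA_real_,
                 lnL_cont = NA_real_, lrt = NA_real_, p_chi2_1df = NA_real_,
                 p_mixture = NA_real_, status = "failed",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write results as TSV plus structured JSON
#'
#' Writes `<prefix>.tsv` (tab-separated, '.' for missing) and
#' `<prefix>.json` containing the same rows plus the run configuration,
#' seeds and filter counts. The JSON layout is described by the schema
#' shipped at `system.file("extdata", "results-schema.json", package =
#' "continuitest")`; [validate_results_json()] checks a file against it.
#'
#' @param df Results table from [results_table()].
#' @param prefix Output path prefix.
#' @param config List of run configuration to embed (flags, seeds).
#' @param filters Filter accounting from [read_dataset()].
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(df, prefix, config = list(), filters = list()) {
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  data.table::fwrite(df, tsv, sep = "\t", na = ".")
  jsonlite::write_json(
    list(results = df, config = config, filters = filters),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null",
    na = "null")
  invisible(c(tsv, js))
}

#' @rdname write_results
#' @param path Path to a results JSON file.
#' @export
validate_results_json <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "results-schema.json",
                                            package = "continuitest"))
  x <- jsonlite::read_json(path)
  for (key in names(schema$required_top_level))
    if (is.null(x[[key]])) stop(sprintf("results JSON lacks '%s'", key), call. = FALSE)
  req <- unlist(schema$required_row_fields)
  for (row in x$results) {
    miss <- setdiff(req, names(row))
    if (length(miss))
      stop(sprintf("results row lacks field(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
  }
  invisible(TRUE)
}
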