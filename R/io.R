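# Readers and writers for the tabular dataset formats, scenario files and
# result exports.  All formats are plain CSV/JSON; genotype codes on disk
# are the count of P1 alleles (2 = P1/P1, 1 = heterozygous, 0 = P2/P2,
# empty = missing) and every individual carries a backcross-origin label.

#' Write a dataset to a directory
#'
#' Writes `map.csv` (chrom, marker, pos_cM), `geno.csv` (id, origin, one
#' column per marker) and `pheno.csv` (env, id, value).
#'
#' @param data A `progeny_data`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "progeny_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$map, file.path(dir, "map.csv"), row.names = FALSE)
  gdf <- data.frame(id = seq_len(nrow(data$geno)), origin = data$origin,
                    line_type = data$line_type)
  gdf <- cbind(gdf, as.data.frame(data$geno))
  utils::write.csv(gdf, file.path(dir, "geno.csv"), row.names = FALSE)
  if (!is.null(data$pheno))
    utils::write.csv(data$pheno, file.path(dir, "pheno.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a dataset from its three CSV files
#'
#' Validates schemas and cross-file consistency: marker sets must agree
#' between map and genotypes, phenotype ids must exist, genotype codes
#' must be consistent with the backcross origin (a BC_P1 individual
#' cannot be homozygous P2, and vice versa), and no (environment,
#' individual) pair may appear twice.  Missing phenotypes are allowed.
#'
#' @param map_path,geno_path,pheno_path File paths; `pheno_path` may be
#'   NULL for a genotypes-only dataset.
#' @return A `progeny_data`.
#' @export
read_dataset <- function(map_path, geno_path, pheno_path = NULL) {
  mp <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "marker", "pos_cM") %in% names(mp)))
    stop("map file ", map_path, ": expected columns chrom, marker, pos_cM",
         call. = FALSE)
  map <- linkage_map(mp$chrom, mp$marker, mp$pos_cM)
  gd <- utils::read.csv(geno_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!all(c("id", "origin") %in% names(gd)))
    stop("genotype file ", geno_path, ": expected columns id, origin",
         call. = FALSE)
  if (anyDuplicated(gd$id))
    stop("genotype file ", geno_path, ": duplicate individual ids",
         call. = FALSE)
  if (!all(gd$origin %in% c("BC_P1", "BC_P2")))
    stop("genotype file ", geno_path,
         ": origin must be 'BC_P1' or 'BC_P2'", call. = FALSE)
  line_type <- if ("line_type" %in% names(gd)) gd$line_type[1] else "DH"
  miss <- setdiff(map$marker, names(gd))
  if (length(miss))
    stop("genotype file ", geno_path, ": missing marker column(s) ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  geno <- as.matrix(gd[, map$marker, drop = FALSE])
  storage.mode(geno) <- "double"
  bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
  if (any(bad))
    stop("genotype file ", geno_path, ": codes must be 0, 1, 2 or missing",
         call. = FALSE)
  p1 <- gd$origin == "BC_P1"
  if (any(geno[p1, ] == 0, na.rm = TRUE))
    stop("genotype file ", geno_path,
         ": P2/P2 homozygote found in a BC_P1 individual", call. = FALSE)
  if (any(geno[!p1, ] == 2, na.rm = TRUE))
    stop("genotype file ", geno_path,
         ": P1/P1 homozygote found in a BC_P2 individual", call. = FALSE)
  pheno <- NULL
  if (!is.null(pheno_path)) {
    ph <- utils::read.csv(pheno_path, stringsAsFactors = FALSE)
    if (!all(c("env", "id", "value") %in% names(ph)))
      stop("phenotype file ", pheno_path,
           ": expected columns env, id, value", call. = FALSE)
    if (!all(ph$id %in% gd$id))
      stop("phenotype file ", pheno_path,
           ": unknown individual id(s)", call. = FALSE)
    if (anyDuplicated(ph[, c("env", "id")]))
      stop("phenotype file ", pheno_path,
           ": duplicate (env, id) record(s)", call. = FALSE)
    ph$id <- match(ph$id, gd$id)
    pheno <- ph[, c("env", "id", "value")]
  }
  structure(list(map = map, geno = geno, origin = gd$origin,
                 line_type = line_type, qtl_geno = NULL, pheno = pheno),
            class = "progeny_data")
}

#' Write / read a QTL scenario as JSON
#'
#' @param scenario A `qtl_scenario`.
#' @param path Output path.
#' @return The path (write) or a `qtl_scenario` (read).
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "qtl_scenario"))
  obj <- list(qtl = scenario$qtl,
              ae = unclass(scenario$ae), de = unclass(scenario$de),
              epistasis = scenario$epistasis, aae = unclass(scenario$aae),
              n_env = scenario$n_env, h2 = scenario$h2, mu = scenario$mu,
              sigma2_env = scenario$sigma2_env)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qtl_scenario(as.data.frame(obj$qtl),
               ae = matrix(unlist(obj$ae), nrow = nrow(obj$qtl)),
               de = matrix(unlist(obj$de), nrow = nrow(obj$qtl)),
               epistasis = if (is.null(obj$epistasis)) NULL else
                 as.data.frame(obj$epistasis),
               aae = if (is.null(obj$epistasis)) NULL else
                 matrix(unlist(obj$aae), nrow = nrow(obj$epistasis)),
               n_env = obj$n_env, h2 = obj$h2, mu = obj$mu,
               sigma2_env = obj$sigma2_env)
}

#' Write a scan profile as CSV
#'
#' @param profile A `scan_profile` or `scan_profile_2d`.
#' @param path Output path.  Positions are in cM; F is the Henderson III
#'   statistic.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' Write a mapping result as JSON
#'
#' @param result A `mapping_result`.
#' @param path Output path.
#' @export
write_mapping_result <- function(result, path) {
  obj <- list(qtl = result$estimates$qtl, pairs = result$estimates$pairs,
              thresholds = result$thresholds,
              cofactors = result$cofactors,
              audit = result$audit)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
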