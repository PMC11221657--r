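#' Diploid genotype matrix for biallelic SNPs
#'
#' Thin container pairing an integer matrix of alt-allele dosages (samples in
#' rows, sites in columns; codes 0/1/2, `NA` = missing call) with its site
#' table. Positions must be strictly increasing within each chromosome.
#'
#' @param geno integer matrix, samples x sites, rownames = sample ids.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @return object of class `geno_matrix` with elements `geno` and `sites`.
#' @export
geno_matrix <- function(geno, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) stop("geno must have sample rownames")
  colnames(geno) <- NULL
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == ncol(geno))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by site index or by sample id
#'
#' @param x a [geno_matrix()].
#' @param sites integer/logical index over sites.
#' @param samples character vector of sample ids (or integer index).
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  g <- x$geno
  s <- x$sites
  if (!is.null(samples)) g <- g[samples, , drop = FALSE]
  if (!is.null(sites)) {
    g <- g[, sites, drop = FALSE]
    s <- s[sites, , drop = FALSE]
  }
  geno_matrix(g, s)
}

GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Write a genotype matrix as a minimal GT-only VCF (v4.2)
#'
#' @param x a [geno_matrix()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=genoflow_",
                      as.character(utils::packageVersion("genoflow"))),
               sprintf("##contig=<ID=%s>", unique(x$sites$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(x$geno)), collapse = "\t"),
             con)
  gt <- matrix("./.", nrow = ncol(x$geno), ncol = nrow(x$geno))
  obs <- !is.na(t(x$geno))
  gt[obs] <- GT_STRINGS[t(x$geno)[obs] + 1L]
  body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Only biallelic SNP records are kept; multi-allelic records are skipped with
#' a message giving the count. Genotypes are decoded from the GT field
#' (phased or unphased); any missing allele gives a missing call.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("no variant records in ", path)
  if (!"GT" %in% unlist(strsplit(v@gt[1L, "FORMAT"], ":")))
    stop("VCF lacks a GT field: ", path)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    message("read_vcf: skipped ", sum(!bi), " multi-allelic record(s)")
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  code[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  sites <- data.frame(chrom = v@fix[, "CHROM"],
                      pos = as.integer(v@fix[, "POS"]),
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      stringsAsFactors = FALSE)
  geno_matrix(t(code), sites)
}

#' Write / read a sample map TSV
#'
#' Columns: `sample`, `species`, `is_reference` (TRUE/FALSE), `basins`
#' (semicolon-separated drainage-basin labels, possibly empty).
#'
#' @param map sample map data.frame.
#' @param path file path.
#' @return `read_sample_map` returns the data.frame.
#' @export
write_sample_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_map
#' @export
read_sample_map <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(basins = "character"))
  m$is_reference <- as.logical(m$is_reference)
  m$basins[is.na(m$basins)] <- ""
  m
}

#' Per-site alt-allele frequencies for a set of samples
#'
#' Missing calls are excluded per site; sites where every sample is missing
#' are returned as `NA` (undefined).
#'
#' @param x a [geno_matrix()].
#' @param samples character vector of sample ids.
#' @return numeric vector of length `n_sites`.
#' @export
allele_frequencies <- function(x, samples) {
  stopifnot(inherits(x, "geno_matrix"))
  missing_ids <- setdiff(samples, rownames(x$geno))
  if (length(missing_ids))
    stop("unknown samples: ", paste(missing_ids, collapse = ", "))
  g <- x$geno[samples, , drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  n <- colSums(!is.na(g))
  out <- alt / (2 * n)
  out[n == 0L] <- NA_real_
  out
}

#' Per-species alt-allele frequency table
#'
#' @param x a [geno_matrix()].
#' @param map sample map.
#' @param species species labels to include (default: all in `map`).
#' @param reference_only use only reference-panel individuals (default TRUE).
#' @return species x site matrix of frequencies (`NA` where undefined).
#' @export
species_frequencies <- function(x, map, species = NULL,
                                reference_only = TRUE) {
  if (is.null(species)) species <- setdiff(unique(map$species), "hybrid")
  rows <- lapply(species, function(s) {
    sel <- map$species == s & (!reference_only | map$is_reference)
    if (!any(sel)) stop("no samples for species ", s)
    allele_frequencies(x, map$sample[sel])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- species
  counts <- do.call(rbind, lapply(species, function(s) {
    sel <- map$species == s & (!reference_only | map$is_reference)
    2L * colSums(!is.na(x$geno[map$sample[sel], , drop = FALSE]))
  }))
  rownames(counts) <- species
  attr(out, "n_alleles") <- counts
  out
}

#' Remove sites with low minor-allele count
#'
#' A site is dropped when its minor-allele count across all non-missing
#' genotypes is below `min_count` (default 3, so that retained variants are
#' seen in more than one individual). Site order is preserved and the filter
#' is idempotent.
#'
#' @param x a [geno_matrix()].
#' @param min_count minimum minor-allele count to keep a site.
#' @return filtered `geno_matrix`.
#' @export
mac_filter <- function(x, min_count = 3L) {
  stopifnot(inherits(x, "geno_matrix"))
  alt <- colSums(x$geno, na.rm = TRUE)
  n2 <- 2L * colSums(!is.na(x$geno))
  mac <- pmin(alt, n2 - alt)
  subset_geno(x, sites = which(mac >= min_count))
}

#' Greedy linkage-disequilibrium pruning
#'
#' Left-to-right scan within each chromosome: each retained site drops any
#' later site within `window_bp` whose squared Pearson correlation of
#' genotype dosages (composite LD; missing calls excluded pairwise) exceeds
#' `r2_threshold`. Zero-variance pairs count as r2 = 0. Deterministic and
#' idempotent.
#'
#' @param x a [geno_matrix()] with sorted sites.
#' @param r2_threshold drop sites with r2 strictly greater than this.
#' @param window_bp pairwise comparison window in bp.
#' @return pruned `geno_matrix`.
#' @export
ld_prune <- function(x, r2_threshold = 0.6, window_bp = 20000L) {
  stopifnot(inherits(x, "geno_matrix"))
  keep <- rep(TRUE, ncol(x$geno))
  pos <- x$sites$pos
  chrom <- x$sites$chrom
  for (i in seq_along(keep)) {
    if (!keep[i]) next
    j <- which(keep & seq_along(keep) > i & chrom == chrom[i] &
               pos - pos[i] <= window_bp)
    if (length(j) == 0L) next
    r <- suppressWarnings(
      cor(x$geno[, i], x$geno[, j, drop = FALSE],
          use = "pairwise.complete.obs"))
    r2 <- as.vector(r)^2
    r2[is.na(r2)] <- 0
    keep[j[r2 > r2_threshold]] <- FALSE
  }
  subset_geno(x, sites = which(keep))
}
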