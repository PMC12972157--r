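#' Encode strain and social rank as model covariates
#'
#' Strain is spread across two true/false traits to avoid imposing a linear
#' ordering on the three strains: "C57BL/6J or Sv129Ev" and "CD1 or C57BL/6J".
#' Social rank is coded ordinally: 0 = subordinate, 1 = neither dominant nor
#' subordinate ("undefined"), 2 = dominant.
#'
#' @param strain Character vector with levels "C57BL/6J", "CD1", "Sv129Ev".
#' @param rank Character vector with levels "subordinate", "undefined",
#'   "dominant".
#' @return data.frame with columns `strain_b6_or_sv`, `strain_cd1_or_b6`
#'   (0/1) and `rank_code` (0/1/2), one row per input element.
#' @export
encode_covariates <- function(strain, rank) {
  stopifnot(length(strain) == length(rank))
  strain_levels <- c("C57BL/6J", "CD1", "Sv129Ev")
  rank_levels <- c("subordinate", "undefined", "dominant")
  bad_s <- setdiff(unique(strain), strain_levels)
  if (length(bad_s) > 0) {
    stop("unknown strain label(s): ", paste(bad_s, collapse = ", "))
  }
  bad_r <- setdiff(unique(rank), rank_levels)
  if (length(bad_r) > 0) {
    stop("unknown rank label(s): ", paste(bad_r, collapse = ", "))
  }
  data.frame(
    strain_b6_or_sv = as.integer(strain %in% c("C57BL/6J", "Sv129Ev")),
    strain_cd1_or_b6 = as.integer(strain %in% c("CD1", "C57BL/6J")),
    rank_code = match(rank, rank_levels) - 1L
  )
}

#' Decode covariate codes back to strain and rank labels
#'
#' Inverse of [encode_covariates()] on the 3x3 label grid.
#'
#' @param strain_b6_or_sv,strain_cd1_or_b6 0/1 codes.
#' @param rank_code Codes in 0:2.
#' @return data.frame with columns `strain` and `rank`.
#' @export
decode_covariates <- function(strain_b6_or_sv, strain_cd1_or_b6, rank_code) {
  stopifnot(all(strain_b6_or_sv %in% 0:1), all(strain_cd1_or_b6 %in% 0:1),
            all(rank_code %in% 0:2))
  if (any(strain_b6_or_sv == 0 & strain_cd1_or_b6 == 0)) {
    stop("strain code (0,0) does not correspond to any strain")
  }
  strain <- ifelse(strain_b6_or_sv == 1 & strain_cd1_or_b6 == 1, "C57BL/6J",
            ifelse(strain_b6_or_sv == 1, "Sv129Ev", "CD1"))
  data.frame(
    strain = strain,
    rank = c("subordinate", "undefined", "dominant")[rank_code + 1L]
  )
}

#' Construct a trait matrix
#'
#' An animals x traits numeric matrix with per-trait metadata. Trait names
#' follow the `<timepoint>_<phase>_<trait>` convention (e.g.
#' `M14_aging_phase_GLU`); covariate traits (rank, the two strain encodings)
#' carry no timepoint and are protected by default.
#'
#' @param values Numeric matrix, animals in rows (rownames = animal ids),
#'   traits in columns (colnames = trait names).
#' @param trait_meta Optional data.frame with columns `trait`, `timepoint`
#'   (label or NA), `category`, `protected` (logical). Inferred from trait
#'   names when omitted.
#' @return Object of class `trait_matrix` (a matrix with a `trait_meta`
#'   attribute).
#' @export
trait_matrix <- function(values, trait_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("trait matrix needs animal rownames and trait colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate animal identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate trait identifiers")
  if (is.null(trait_meta)) trait_meta <- infer_trait_meta(colnames(values))
  stopifnot(identical(sort(trait_meta$trait), sort(colnames(values))))
  trait_meta <- trait_meta[match(colnames(values), trait_meta$trait), ]
  rownames(trait_meta) <- NULL
  structure(values, trait_meta = trait_meta, class = c("trait_matrix", "matrix", "array"))
}

# internal: parse `<timepoint>_<phase>_<trait>` names; covariates have no
# timepoint and are protected
infer_trait_meta <- function(trait_names) {
  tp_labels <- names(timepoint_grid())
  covariates <- c("rank_code", "strain_b6_or_sv", "strain_cd1_or_b6")
  parts <- strsplit(trait_names, "_")
  timepoint <- vapply(parts, function(p) {
    if (p[1] %in% tp_labels) p[1] else NA_character_
  }, character(1))
  category <- vapply(seq_along(parts), function(i) {
    nm <- trait_names[i]
    if (nm %in% covariates) {
      if (nm == "rank_code") "rank" else "strain"
    } else if (grepl("_aging_phase_", nm)) {
      tolower(sub(".*_aging_phase_", "", nm))
    } else {
      tolower(nm)
    }
  }, character(1))
  data.frame(
    trait = trait_names,
    timepoint = timepoint,
    category = category,
    protected = trait_names %in% covariates
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d animals x %d traits (%d protected)\n",
              nrow(x), ncol(x), sum(attr(x, "trait_meta")$protected)))
  invisible(x)
}

#' Construct a methylation matrix
#'
#' @param values Numeric matrix of beta values, animals in rows, CpG sites in
#'   columns; rownames = animal ids, colnames = site ids.
#' @param build Genome build tag for the site ids ("mm39" or "mm10").
#' @param scale Either "beta" (values must lie in `[0,1]`) or "mvalue".
#' @return Object of class `meth_matrix`.
#' @export
meth_matrix <- function(values, build = "mm39", scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("methylation matrix needs animal rownames and site colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate animal identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate site identifiers")
  if (scale == "beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1))
    if (length(bad) > 0) {
      rc <- arrayInd(bad[1], dim(values))
      stop(sprintf("beta value out of [0,1] at animal %s, site %s: %g",
                   rownames(values)[rc[1]], colnames(values)[rc[2]],
                   values[bad[1]]))
    }
  }
  structure(values, build = build, scale = scale,
            class = c("meth_matrix", "matrix", "array"))
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d animals x %d sites (%s, %s values)\n",
              nrow(x), ncol(x), attr(x, "build"), attr(x, "scale")))
  invisible(x)
}

#' Read and write trait tables
#'
#' Wide CSV dialect: one row per animal, first column `animal_id`, remaining
#' columns named `<timepoint>_<phase>_<trait>` or a covariate name. Empty
#' cells are read as missing (never as zero).
#'
#' @param path File path.
#' @return `read_trait_table` returns a [trait_matrix()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(df)) stop("trait table must have an animal_id column")
  ids <- as.character(df$animal_id)
  num <- df[setdiff(names(df), "animal_id")]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (is.character(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(conv))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric cell at row %d, column %s: '%s'",
                     bad[1], names(num)[j], col[bad[1]]))
      }
      conv[col == ""] <- NA_real_
      num[[j]] <- conv
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  trait_matrix(m)
}

#' @param traits A [trait_matrix()].
#' @rdname read_trait_table
#' @export
write_trait_table <- function(traits, path) {
  df <- data.frame(animal_id = rownames(traits),
                   as.data.frame(unclass(traits)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write methylation matrices
#'
#' Array-export-like CSV dialect: sites in rows, animals in columns, first
#' column `site_id`; the matrix is transposed to animals x sites on load.
#' Beta values outside `[0,1]` are a validation error.
#'
#' @param path File path.
#' @param build Genome build tag of the site ids.
#' @param scale "beta" or "mvalue".
#' @return `read_methylation` returns a [meth_matrix()].
#' @export
read_methylation <- function(path, build = "mm39", scale = "beta") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(df)) stop("methylation table must have a site_id column")
  sites <- as.character(df$site_id)
  m <- t(as.matrix(df[setdiff(names(df), "site_id")]))
  colnames(m) <- sites
  storage.mode(m) <- "double"
  meth_matrix(m, build = build, scale = scale)
}

#' @param meth A [meth_matrix()].
#' @rdname read_methylation
#' @export
write_methylation <- function(meth, path) {
  df <- data.frame(site_id = colnames(meth),
                   as.data.frame(t(unclass(meth))), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Map site ids across genome builds
#'
#' Applies a two-column lookup table (source id, target id); no coordinate
#' arithmetic is performed. Sites absent from the table are dropped and
#' counted, preserving the input order of the mapped sites.
#'
#' @param sites Character vector of source-build site ids.
#' @param mapping data.frame with columns `source` and `target`.
#' @return List with `mapped` (target ids, in input order), `kept` (logical
#'   mask over the input), and `n_dropped`.
#' @export
map_sites <- function(sites, mapping) {
  stopifnot(all(c("source", "target") %in% names(mapping)))
  if (anyDuplicated(mapping$source)) {
    stop("duplicate source keys in mapping table")
  }
  idx <- match(sites, mapping$source)
  kept <- !is.na(idx)
  list(mapped = mapping$target[idx[kept]],
       kept = kept,
       n_dropped = sum(!kept))
}

#' Export a site list as BED
#'
#' Writes a 4-column BED file (0-based half-open intervals) for handoff to
#' external enrichment tools.
#'
#' @param site_table data.frame with columns `chrom`, `start`, `end`,
#'   `site_id`.
#' @param path Output path.
#' @export
write_sites_bed <- function(site_table, path) {
  stopifnot(all(c("chrom", "start", "end", "site_id") %in% names(site_table)))
  stopifnot(all(site_table$end > site_table$start), all(site_table$start >= 0))
  utils::write.table(site_table[, c("chrom", "start", "end", "site_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
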