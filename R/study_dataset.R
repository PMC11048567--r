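#' Assemble a gradient study dataset
#'
#' A study dataset bundles the plot-by-species mean-cover matrix with plot
#' metadata and species attributes. Plots are arranged five per transect
#' along an invasion gradient and labelled A (completely invaded, invader
#' relative cover above 20 percent) through E (uninvaded, below 5 percent);
#' plot C sits near the edge of the invasive population.
#'
#' @param cover Numeric matrix of mean percent cover, plots in rows (row
#'   names are plot ids), species in columns.
#' @param plots Data frame with columns \code{plot_id}, \code{transect_id}
#'   and \code{group} (one of A-E), one row per plot.
#' @param species Data frame of species attributes with columns
#'   \code{species}, \code{native} (logical), \code{c_value} (coefficient of
#'   conservatism, integer 0-10 or \code{NA}) and \code{invader} (logical;
#'   member of the target-invader set -- a taxon may be flagged invasive while
#'   native, as regulated cattails are).
#' @param target_invader Character vector naming the analysis's target
#'   invader taxon or taxa; defaults to all invader-flagged species.
#' @return A validated object of class \code{study_dataset} with elements
#'   \code{cover}, \code{plots}, \code{species}, \code{target_invader}.
#' @seealso [read_study()], [write_study()], [generate_study()]
#' @export
study_dataset <- function(cover, plots, species, target_invader = NULL) {
  cover <- as.matrix(cover)
  storage.mode(cover) <- "double"
  plots <- as.data.frame(plots, stringsAsFactors = FALSE)
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(target_invader))
    target_invader <- species$species[isTRUE_vec(species$invader)]
  # canonical ordering: plots by transect then group, species alphabetical
  ord <- order(plots$transect_id, plots$group)
  plots <- plots[ord, , drop = FALSE]
  rownames(plots) <- NULL
  cover <- cover[match(plots$plot_id, rownames(cover)), , drop = FALSE]
  cover <- cover[, order(colnames(cover)), drop = FALSE]
  x <- structure(
    list(cover = cover, plots = plots, species = species,
         target_invader = target_invader),
    class = "study_dataset"
  )
  validate_study_dataset(x)
  x
}

isTRUE_vec <- function(x) !is.na(x) & x

validate_study_dataset <- function(x) {
  stopifnot(inherits(x, "study_dataset"))
  plots <- x$plots; species <- x$species; cover <- x$cover
  req <- c("plot_id", "transect_id", "group")
  if (!all(req %in% names(plots)))
    stop("plot metadata must have columns ", paste(req, collapse = ", "))
  reqs <- c("species", "native", "c_value", "invader")
  if (!all(reqs %in% names(species)))
    stop("species attributes must have columns ", paste(reqs, collapse = ", "))
  if (anyDuplicated(species$species))
    stop("duplicated species in attributes table: ",
         paste(unique(species$species[duplicated(species$species)]), collapse = ", "))
  if (anyDuplicated(plots$plot_id))
    stop("duplicated plot ids: ",
         paste(unique(plots$plot_id[duplicated(plots$plot_id)]), collapse = ", "))
  if (!all(plots$group %in% c("A", "B", "C", "D", "E")))
    stop("plot group labels must be A, B, C, D or E")
  if (!identical(rownames(cover), plots$plot_id))
    stop("cover matrix rows must match plot metadata")
  if (any(cover < 0)) stop("cover values must be non-negative")
  # every transect carries exactly one plot per gradient position
  for (tr in unique(plots$transect_id)) {
    g <- sort(plots$group[plots$transect_id == tr])
    if (!identical(g, c("A", "B", "C", "D", "E")))
      stop("transect ", tr, " does not have exactly one plot per group A-E",
           " (found: ", paste(g, collapse = ", "), ")")
  }
  unknown <- setdiff(colnames(cover), species$species)
  if (length(unknown))
    stop("species in community table without an attributes row: ",
         paste(unknown, collapse = ", "))
  cv <- species$c_value
  if (any(!is.na(cv) & (cv < 0 | cv > 10)))
    stop("c_value must lie in [0, 10] where present")
  ti <- x$target_invader
  if (length(ti) == 0L) stop("no target invader defined")
  bad <- setdiff(ti, species$species[isTRUE_vec(species$invader)])
  if (length(bad))
    stop("target invader not flagged in attributes: ", paste(bad, collapse = ", "))
  invisible(x)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Invasion-gradient study dataset\n")
  cat(sprintf("  %d plots on %d transects (5 per transect, groups A-E)\n",
              nrow(x$plots), length(unique(x$plots$transect_id))))
  cat(sprintf("  %d species recorded (%d native); target invader: %s\n",
              ncol(x$cover), sum(isTRUE_vec(x$species$native) &
                                   x$species$species %in% colnames(x$cover)),
              paste(x$target_invader, collapse = " + ")))
  invisible(x)
}

#' Plot-by-species cover matrix of a study dataset
#' @param dataset A \code{study_dataset}.
#' @return Numeric matrix, plots in rows, species in columns.
#' @export
cover_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  dataset$cover
}

#' Read a gradient study from community and attribute tables
#'
#' The canonical community format is a long, comma-delimited table with
#' header \code{plot_id, transect_id, group, species, cover_pct} (one row
#' per species occurrence; absences omitted). A wide layout -- the first
#' three columns \code{plot_id, transect_id, group} followed by one column
#' per species -- is accepted read-only. The attributes table has columns
#' \code{species, native, c_value, invader}.
#'
#' @param community_file Path to the community table (long or wide CSV).
#' @param attributes_file Path to the species-attributes CSV.
#' @param target_invader Optional target invader name(s); defaults to every
#'   invader-flagged species in the attributes table.
#' @param aliases Optional named character vector mapping recorded species
#'   names to analysis taxa (for example collapsing congeneric cattails onto
#'   one aggregate taxon); covers of aliased names are summed.
#' @return A \code{\link{study_dataset}}.
#' @export
read_study <- function(community_file, attributes_file,
                       target_invader = NULL, aliases = NULL) {
  comm <- utils::read.csv(community_file, stringsAsFactors = FALSE,
                          check.names = FALSE)
  attrs <- utils::read.csv(attributes_file, stringsAsFactors = FALSE)
  reqa <- c("species", "native", "c_value", "invader")
  if (!all(reqa %in% names(attrs)))
    stop("attributes table must have columns ", paste(reqa, collapse = ", "))
  attrs$native <- as_flag(attrs$native, "native")
  attrs$invader <- as_flag(attrs$invader, "invader")
  attrs$c_value <- suppressWarnings(as.numeric(attrs$c_value))

  long_cols <- c("plot_id", "transect_id", "group", "species", "cover_pct")
  if (all(long_cols %in% names(comm))) {
    long <- comm[long_cols]
  } else if (all(c("plot_id", "transect_id", "group") %in% names(comm)[1:3])) {
    sp_cols <- setdiff(names(comm), c("plot_id", "transect_id", "group"))
    long <- do.call(rbind, lapply(sp_cols, function(sp) {
      data.frame(plot_id = comm$plot_id, transect_id = comm$transect_id,
                 group = comm$group, species = sp,
                 cover_pct = comm[[sp]], stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$cover_pct) & long$cover_pct != 0, , drop = FALSE]
  } else {
    stop("community table is neither long (plot_id, transect_id, group, ",
         "species, cover_pct) nor wide (plot_id, transect_id, group, ",
         "then species columns)")
  }

  cov_num <- suppressWarnings(as.numeric(long$cover_pct))
  if (anyNA(cov_num))
    stop("non-numeric cover at community table row(s): ",
         paste(which(is.na(cov_num)), collapse = ", "))
  long$cover_pct <- cov_num

  if (!is.null(aliases)) {
    hit <- long$species %in% names(aliases)
    long$species[hit] <- unname(aliases[long$species[hit]])
    if (!is.null(target_invader) && any(target_invader %in% names(aliases)))
      target_invader <- unique(unname(aliases[target_invader]))
  }
  key <- paste(long$plot_id, long$species, sep = "\r")
  if (!is.null(aliases)) {
    # aliasing may legitimately merge rows: sum them
    agg <- stats::aggregate(cover_pct ~ plot_id + transect_id + group + species,
                            data = long, FUN = sum)
    long <- agg
  } else if (anyDuplicated(key)) {
    d <- long[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("duplicate (plot, species) rows in community table: ",
         paste(unique(paste0(d$plot_id, "/", d$species)), collapse = ", "))
  }

  plot_ids <- unique(long$plot_id)
  meta <- long[!duplicated(long$plot_id), c("plot_id", "transect_id", "group")]
  species <- sort(unique(long$species))
  cover <- matrix(0, nrow = length(plot_ids), ncol = length(species),
                  dimnames = list(plot_ids, species))
  cover[cbind(match(long$plot_id, plot_ids),
              match(long$species, species))] <- long$cover_pct
  study_dataset(cover, meta, attrs, target_invader = target_invader)
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("column '", what, "' must be true/false")
  out
}

#' Write a study dataset to community and attribute tables
#'
#' Writes the canonical long-form community CSV (only non-zero covers) and
#' the species-attributes CSV, such that \code{read_study()} on the two
#' files reconstructs the dataset exactly.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param community_file,attributes_file Output paths.
#' @return Invisibly, the dataset.
#' @export
write_study <- function(dataset, community_file, attributes_file) {
  stopifnot(inherits(dataset, "study_dataset"))
  cov <- dataset$cover
  idx <- which(cov > 0, arr.ind = TRUE)
  long <- data.frame(
    plot_id = rownames(cov)[idx[, 1L]],
    transect_id = dataset$plots$transect_id[idx[, 1L]],
    group = dataset$plots$group[idx[, 1L]],
    species = colnames(cov)[idx[, 2L]],
    cover_pct = cov[idx],
    stringsAsFactors = FALSE
  )
  long <- long[order(long$plot_id, long$species), , drop = FALSE]
  # keep every plot present even if (degenerately) all-zero: impossible for
  # generated data, but guard the round-trip anyway
  missing_plots <- setdiff(dataset$plots$plot_id, long$plot_id)
  if (length(missing_plots))
    stop("plot(s) with no recorded species cannot be serialised in long form: ",
         paste(missing_plots, collapse = ", "))
  utils::write.csv(long, community_file, row.names = FALSE, quote = TRUE)
  utils::write.csv(dataset$species, attributes_file, row.names = FALSE,
                   quote = TRUE)
  invisible(dataset)
}
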