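#' Permanence classes belonging to a hydroperiod group
#'
#' The four permanence classes partition into a short-hydroperiod group
#' (temporary + seasonal) and a long-hydroperiod group (semi-permanent +
#' permanent); \code{"all"} covers every class.
#'
#' @param label one of \code{"short"}, \code{"long"}, \code{"all"}.
#' @return character vector of permanence classes.
#' @export
hydroGroupClasses <- function(label = c("all", "short", "long")) {
    label <- match.arg(label)
    switch(label,
           short = c("temporary", "seasonal"),
           long  = c("semi-permanent", "permanent"),
           all   = PERMANENCE_CLASSES)
}

.validateMetadata <- function(meta, path = "metadata") {
    required <- c("site_id", "permanence_class", "days_ponded",
                  "max_depth_cm", "amplitude_ratio", "evap_index")
    missing <- setdiff(required, names(meta))
    if (length(missing))
        stop(sprintf("%s: missing column(s): %s", path,
                     paste(missing, collapse = ", ")))
    meta$site_id <- as.character(meta$site_id)
    dup <- unique(meta$site_id[duplicated(meta$site_id)])
    if (length(dup))
        stop(sprintf("%s: duplicate site ID(s): %s", path,
                     paste(dup, collapse = ", ")))
    bad <- setdiff(unique(meta$permanence_class), PERMANENCE_CLASSES)
    if (length(bad))
        stop(sprintf("%s: unknown permanence class(es) %s; allowed values are: %s",
                     path, paste(sQuote(bad), collapse = ", "),
                     paste(PERMANENCE_CLASSES, collapse = ", ")))
    num <- c("days_ponded", "max_depth_cm", "amplitude_ratio", "evap_index")
    if (anyNA(meta[num]))
        stop(sprintf("%s: missing values in hydroperiod indicators", path))
    if (any(meta$days_ponded < 0 | meta$days_ponded > 365))
        stop(sprintf("%s: days_ponded outside [0, 365]", path))
    if (any(meta$amplitude_ratio < 0 | meta$amplitude_ratio > 1))
        stop(sprintf("%s: amplitude_ratio outside [0, 1]", path))
    if (any(meta$max_depth_cm < 0))
        stop(sprintf("%s: negative max_depth_cm", path))
    meta
}

.hydroFromMetadata <- function(meta) {
    v <- as.matrix(meta[, c("days_ponded", "max_depth_cm",
                            "amplitude_ratio", "evap_index")])
    colnames(v) <- HYDRO_VARIABLES
    rownames(v) <- meta$site_id
    hydroperiodMatrix(v)
}

.readCommunityCSV <- function(path, label, exclude = NULL) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop(sprintf("%s: expected a site-ID column plus at least 2 taxa", path))
    ids <- as.character(df[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop(sprintf("%s: duplicate site ID(s): %s", path,
                     paste(dup, collapse = ", ")))
    v <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(v))
        stop(sprintf("%s: non-numeric abundance values", path))
    rownames(v) <- ids
    if (!is.null(exclude)) {
        dropped <- intersect(exclude, colnames(v))
        if (length(dropped)) {
            message(sprintf("%s [%s]: excluding %d column(s): %s", path, label,
                            length(dropped), paste(dropped, collapse = ", ")))
            v <- v[, setdiff(colnames(v), dropped), drop = FALSE]
        }
    }
    if (anyNA(v))
        stop(sprintf("%s: missing abundance cells; blanks are data errors, not zeros", path))
    if (any(v < 0))
        stop(sprintf("%s: negative abundance values", path))
    communityMatrix(v, label)
}

#' Load a multi-community wetland dataset from CSV files
#'
#' Reads one site-by-taxon CSV per horizontal community (first column =
#' site ID, remaining columns = taxa) plus a site metadata CSV with
#' columns \code{site_id}, \code{permanence_class}, \code{days_ponded},
#' \code{max_depth_cm}, \code{amplitude_ratio}, \code{evap_index}.
#' All validation is hard: duplicate or missing site IDs, negative or
#' blank abundances, and unknown permanence classes raise errors naming
#' the offending values. A validation summary (sites per permanence
#' class, taxa per community) is emitted as a message.
#'
#' @param communityPaths named character vector of CSV paths; names are
#'   the community labels.
#' @param metadataPath path to the site metadata CSV.
#' @param exclude optional named list (by community label) of column names
#'   to drop before validation, e.g. non-vascular cover classes in a
#'   plant table; exclusions are logged.
#' @return a list with elements \code{communities} (named list of
#'   [CommunityMatrix-class]), \code{metadata} (validated data.frame) and
#'   \code{hydro} ([HydroperiodMatrix-class] built from the metadata
#'   indicator columns). Matrices are not yet row-aligned; see
#'   [alignSites()].
#' @export
loadDataset <- function(communityPaths, metadataPath, exclude = NULL) {
    if (is.null(names(communityPaths)) || any(!nzchar(names(communityPaths))))
        stop("communityPaths must be a named vector (names = community labels)")
    for (p in c(communityPaths, metadataPath))
        if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    communities <- lapply(names(communityPaths), function(lab)
        .readCommunityCSV(communityPaths[[lab]], lab, exclude[[lab]]))
    names(communities) <- names(communityPaths)
    meta <- .validateMetadata(
        utils::read.csv(metadataPath, stringsAsFactors = FALSE), metadataPath)
    classCounts <- table(factor(meta$permanence_class, PERMANENCE_CLASSES))
    message(sprintf("loaded %d communities; %d metadata sites (%s)",
                    length(communities), nrow(meta),
                    paste(sprintf("%s=%d", names(classCounts), classCounts),
                          collapse = ", ")))
    for (lab in names(communities))
        message(sprintf("  %s: %d sites x %d taxa", lab,
                        nrow(communities[[lab]]), ncol(communities[[lab]])))
    list(communities = communities, metadata = meta,
         hydro = .hydroFromMetadata(meta))
}

#' Align all matrices of a dataset on a common ordered site set
#'
#' Procrustes superimposition requires row-matched matrices. This
#' restricts every community matrix, the metadata and the hydroperiod
#' matrix to the intersection of their site IDs, ordered
#' lexicographically, and logs any dropped sites. Aligning an already
#' aligned dataset is a no-op.
#'
#' @param dataset a list as returned by [loadDataset()] (elements
#'   \code{communities}, \code{metadata}, \code{hydro}).
#' @return the same structure with identical \code{siteIds()} in
#'   identical (lexicographic) order everywhere.
#' @export
alignSites <- function(dataset) {
    idSets <- c(lapply(dataset$communities, siteIds),
                list(hydro = siteIds(dataset$hydro),
                     metadata = dataset$metadata$site_id))
    common <- Reduce(intersect, idSets)
    if (length(common) < 3L)
        stop(sprintf("site intersection across matrices has %d site(s); at least 3 are required",
                     length(common)))
    common <- sort(common)
    for (nm in names(idSets)) {
        dropped <- setdiff(idSets[[nm]], common)
        if (length(dropped))
            message(sprintf("alignSites: dropping %d site(s) from %s (absent elsewhere): %s",
                            length(dropped), nm, paste(dropped, collapse = ", ")))
    }
    communities <- lapply(dataset$communities, function(cm)
        communityMatrix(abundances(cm)[common, , drop = FALSE],
                        communityLabel(cm)))
    meta <- dataset$metadata[match(common, dataset$metadata$site_id), , drop = FALSE]
    rownames(meta) <- NULL
    list(communities = communities, metadata = meta,
         hydro = hydroperiodMatrix(indicators(dataset$hydro)[common, , drop = FALSE]))
}

#' Sites belonging to a hydroperiod group
#'
#' @param metadata validated site metadata data.frame (columns
#'   \code{site_id}, \code{permanence_class}).
#' @param label \code{"short"} (temporary + seasonal), \code{"long"}
#'   (semi-permanent + permanent) or \code{"all"}.
#' @return sorted character vector of the member site IDs.
#' @examples
#' meta <- data.frame(site_id = paste0("W", 1:5),
#'                    permanence_class = c("temporary", "seasonal",
#'                                         "seasonal", "permanent",
#'                                         "semi-permanent"))
#' assignGroup(meta, "short")
#' @export
assignGroup <- function(metadata, label = c("all", "short", "long")) {
    label <- match.arg(label)
    classes <- hydroGroupClasses(label)
    bad <- setdiff(unique(metadata$permanence_class), PERMANENCE_CLASSES)
    if (length(bad))
        stop(sprintf("unknown permanence class(es) %s; allowed values are: %s",
                     paste(sQuote(bad), collapse = ", "),
                     paste(PERMANENCE_CLASSES, collapse = ", ")))
    ids <- sort(as.character(metadata$site_id[metadata$permanence_class %in% classes]))
    if (length(ids) == 0L)
        stop(sprintf("hydroperiod group '%s' contains no sites", label))
    message(sprintf("group '%s': %d sites", label, length(ids)))
    ids
}
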