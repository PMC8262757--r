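#' Annotate a plasmid against one or more feature libraries
#'
#' Runs the full pipeline: validate the record, double the sequence for
#' circular topology, search every library, apply per-library E-value and
#' identity cutoffs, localize hits back onto the plasmid, pool hits across
#' libraries, score them, resolve overlaps with the trimmed-core greedy
#' filter, and flag feature fragments. The result is deterministic for a
#' given record, library set, configuration, and internal or precomputed
#' backend.
#'
#' @param record A [sequence_record()].
#' @param libraries A single [feature_library()] or a list of them.
#' @param backends A single [search_backend()] applied to every library,
#'   or a named list keyed by `library_tag`. Defaults to the internal
#'   backend.
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage hit-count messages.
#' @return An `annotation_report`: the record, the kept hits (tibble in
#'   filter scan order, with feature metadata, priority score, display
#'   score, and fragment flags), the configuration snapshot, and a library
#'   manifest.
#' @export
#' @examples
#' lib <- generate_toy_library(3, seed = 1)
#' toy <- plant_features(lib, layout = toy_layout(lib$entries$entry_id[1]),
#'                       seed = 2)
#' rep <- annotate(toy$record, lib, quiet = TRUE)
#' tidy(rep)
annotate <- function(record, libraries, backends = NULL,
                     config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(record, "seq_record"))
  if (inherits(libraries, "feature_library")) libraries <- list(libraries)
  if (length(libraries) == 0) abort_input("no libraries supplied")
  for (lib in libraries) stopifnot(inherits(lib, "feature_library"))
  if (inherits(backends, "search_backend")) {
    backends <- stats::setNames(
      rep(list(backends), length(libraries)),
      vapply(libraries, `[[`, character(1), "library_tag"))
  }

  record <- validate_sequence(record, config)
  ws <- prepare_working_sequence(record)
  L <- ws$plasmid_length

  say <- function(...) if (!quiet) message(sprintf(...))
  pooled <- purrr::map(libraries, function(lib) {
    backend <- backends[[lib$library_tag]] %||% search_backend("internal")
    raw <- search_library(ws$working, lib, backend, config)
    cut <- apply_cutoffs(raw, lib)
    loc <- localize_hits(cut, L, record$topology)
    say("[%s] %d raw -> %d post-cutoff -> %d localized hits",
        lib$library_tag, nrow(raw), nrow(cut), nrow(loc))
    meta <- dplyr::select(lib$entries, dplyr::all_of(
      c("entry_id", "name", "type_key", "description")))
    dplyr::left_join(loc, meta, by = "entry_id")
  })
  pooled <- dplyr::bind_rows(pooled)

  scored <- compute_priority_score(pooled)
  kept <- resolve_overlaps(scored, L, record$topology, config$trim_frac)
  kept <- flag_fragment(kept, config$fragment_threshold)
  kept <- compute_display_score(kept)
  say("filter kept %d of %d pooled hits (%d fragment%s)",
      nrow(kept), nrow(pooled), sum(kept$is_fragment),
      if (sum(kept$is_fragment) == 1) "" else "s")

  manifest <- purrr::map(libraries, function(lib) {
    tibble::tibble(library_tag = lib$library_tag,
                   n_entries = nrow(lib$entries),
                   search_kind = lib$search_kind,
                   evalue_cutoff = lib$evalue_cutoff,
                   identity_cutoff = lib$identity_cutoff)
  })
  structure(
    list(record = record, kept_hits = kept, config = config,
         library_manifest = dplyr::bind_rows(manifest)),
    class = "annotation_report"
  )
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("<annotation_report> %s (%s, %s bp): %d feature(s), %d fragment(s)\n",
              x$record$identifier, x$record$topology,
              format(nchar(x$record$sequence), big.mark = ","),
              nrow(x$kept_hits), sum(x$kept_hits$is_fragment)))
  if (nrow(x$kept_hits) > 0) {
    print(dplyr::select(x$kept_hits, dplyr::all_of(
      c("name", "start", "end", "strand", "library_tag", "identity",
        "subject_cov", "priority", "is_fragment"))))
  }
  invisible(x)
}

#' Tidy an annotation report into a tibble of kept hits
#'
#' @param x An `annotation_report`.
#' @param ... Unused.
#' @return A tibble, one row per kept feature, in filter scan order.
#' @method tidy annotation_report
#' @export
tidy.annotation_report <- function(x, ...) {
  x$kept_hits
}

#' One-row summary of an annotation report
#'
#' @param x An `annotation_report`.
#' @param ... Unused.
#' @return A one-row tibble: sequence length, topology, feature and
#'   fragment counts, and the fraction of plasmid bases covered by
#'   fragment hits (`fragment_occupancy`).
#' @method glance annotation_report
#' @export
glance.annotation_report <- function(x, ...) {
  L <- nchar(x$record$sequence)
  hits <- x$kept_hits
  tibble::tibble(
    identifier = x$record$identifier,
    seq_length = L,
    topology = x$record$topology,
    n_features = nrow(hits),
    n_fragments = sum(hits$is_fragment),
    fragment_occupancy = fragment_occupancy(x)
  )
}

#' Fraction of plasmid bases covered by fragment hits
#'
#' Computes the proportion of the plasmid's bases lying under at least one
#' kept hit flagged as a feature fragment.
#'
#' @param report An `annotation_report`.
#' @return A fraction in `[0, 1]`.
#' @export
fragment_occupancy <- function(report) {
  L <- nchar(report$record$sequence)
  hits <- report$kept_hits[report$kept_hits$is_fragment, , drop = FALSE]
  if (nrow(hits) == 0) return(0)
  covered <- logical(L)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]
    e <- if (hits$spans_origin[i]) hits$end[i] + L else hits$end[i]
    pos <- (seq.int(s, e - 1) %% L) + 1
    covered[pos] <- TRUE
  }
  mean(covered)
}

#' Plot an annotation report as a linear feature map
#'
#' Draws each kept feature as an arrow along the sequence axis, coloured
#' by source library; fragments are drawn hollow (unfilled), complete
#' features solid. Origin-spanning features appear as two segments.
#'
#' @param object An `annotation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot annotation_report
#' @export
autoplot.annotation_report <- function(object, ...) {
  L <- nchar(object$record$sequence)
  hits <- object$kept_hits
  if (nrow(hits) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::xlim(0, L) +
             ggplot2::labs(title = object$record$identifier,
                           x = "position (bp)"))
  }
  segs <- purrr::pmap(hits, function(...) {
    h <- list(...)
    if (h$spans_origin) {
      tibble::tibble(name = h$name, library_tag = h$library_tag,
                     is_fragment = h$is_fragment, strand = h$strand,
                     xmin = c(h$start, 0), xmax = c(L, h$end))
    } else {
      tibble::tibble(name = h$name, library_tag = h$library_tag,
                     is_fragment = h$is_fragment, strand = h$strand,
                     xmin = h$start, xmax = h$end)
    }
  })
  segs <- dplyr::bind_rows(segs, .id = "hit")
  segs$lane <- as.integer(factor(segs$hit))
  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$lane - 0.4, ymax = .data$lane + 0.4,
                   colour = .data$library_tag,
                   fill = ifelse(.data$is_fragment, NA, .data$library_tag)),
      linewidth = 0.6, na.rm = TRUE) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$xmin + .data$xmax) / 2, y = .data$lane,
                   label = .data$name), size = 3, check_overlap = TRUE) +
    ggplot2::scale_fill_discrete(na.value = NA, guide = "none") +
    ggplot2::labs(title = object$record$identifier, x = "position (bp)",
                  y = NULL, colour = "library") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
plot.annotation_report <- function(x, ...) print(autoplot.annotation_report(x, ...))

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
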