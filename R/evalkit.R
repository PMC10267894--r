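# Retrieval evaluation: top-k curves, rank products, random-annotation
# baselines and structure-similarity-vs-rank profiles.

#' Rank every validation record against a library
#'
#' Runs the chosen search for each record and reports the rank of its true
#' molecule. With `combine = TRUE`, records are grouped by metabolite and
#' the per-adduct hit lists are merged with [combine_adducts()] before
#' ranking, so the unit of evaluation becomes the metabolite.
#'
#' @param records Validation records tibble (see
#'   [build_synthetic_benchmark()]): columns `record_id`, `metabolite_id`,
#'   `molecule_id` (truth), `adduct`, `precursor_mz`, `spectrum`.
#' @param lib `ir_library`.
#' @param mode `"isomer"` or `"unsupervised"`.
#' @param combine Combine adducts of the same metabolite by score product?
#' @param energy_tol Energy tolerance in kJ/mol passed to the search.
#' @param tol_ppm Isomer-mode m/z window in ppm.
#' @return Tibble with one row per record (or per metabolite when
#'   combining): `unit_id`, `molecule_id`, `rank`, `n_candidates`, `s_spec`
#'   (score of the true molecule; product score when combined).
#' @export
rank_records <- function(records, lib, mode = c("isomer", "unsupervised"),
                         combine = FALSE, energy_tol = 0, tol_ppm = 10) {
  mode <- match.arg(mode)
  if (any(is.na(records$molecule_id))) {
    stop("validation record without true molecule id", call. = FALSE)
  }
  missing <- setdiff(records$molecule_id, lib$entries$molecule_id)
  if (length(missing) > 0L) {
    stop("true molecule(s) absent from library: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hit_list <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    search_library(lib, r$spectrum[[1]], r$adduct, mode = mode,
                   precursor_mz = r$precursor_mz, tol_ppm = tol_ppm,
                   energy_tol = energy_tol)
  })
  if (!combine) {
    return(purrr::map_dfr(seq_len(nrow(records)), function(i) {
      h <- hit_list[[i]]
      tibble::tibble(
        unit_id = records$record_id[i],
        molecule_id = records$molecule_id[i],
        rank = rank_of(h, records$molecule_id[i]),
        n_candidates = nrow(h),
        s_spec = h$s_spec[h$molecule_id == records$molecule_id[i]][1]
      )
    }))
  }
  groups <- split(seq_len(nrow(records)), records$metabolite_id)
  purrr::map_dfr(names(groups)[order(names(groups))], function(g) {
    idx <- groups[[g]]
    combined <- combine_adducts(hit_list[idx])
    truth <- records$molecule_id[idx[1]]
    tibble::tibble(
      unit_id = g,
      molecule_id = truth,
      rank = rank_of(combined, truth),
      n_candidates = nrow(combined),
      s_spec = combined$combined_score[combined$molecule_id == truth][1]
    )
  })
}

#' Top-k identification curve
#'
#' Percentage of validation units whose true molecule is ranked within the
#' top k, for k = 1..k_max.
#'
#' @inheritParams rank_records
#' @param k_max Largest k reported.
#' @param ranks Optional precomputed result of [rank_records()]; when given,
#'   `records`/`lib` are not needed.
#' @return Tibble with columns `k` and `percent` (monotone non-decreasing,
#'   <= 100).
#' @export
topk_curve <- function(records = NULL, lib = NULL,
                       mode = c("isomer", "unsupervised"), combine = FALSE,
                       k_max = 10, energy_tol = 0, tol_ppm = 10,
                       ranks = NULL) {
  if (is.null(ranks)) {
    ranks <- rank_records(records, lib, mode = mode, combine = combine,
                          energy_tol = energy_tol, tol_ppm = tol_ppm)
  }
  r <- ranks$rank
  tibble::tibble(
    k = seq_len(k_max),
    percent = vapply(seq_len(k_max),
                     function(k) 100 * mean(r <= k), numeric(1))
  )
}

#' Rank product of a validation set
#'
#' Geometric mean of the ranks of the true structures,
#' \eqn{RP = (\prod_i r_i)^{1/N}}, computed in log space for numerical
#' stability. RP = 1 means every structure ranked first.
#'
#' @param ranks Vector of positive integer ranks.
#' @return RP >= 1.
#' @export
#' @examples
#' rank_product(c(10, 20, 6)) # 1200^(1/3)
rank_product <- function(ranks) {
  if (length(ranks) == 0L) stop("empty rank list", call. = FALSE)
  if (any(ranks < 1)) stop("ranks must be >= 1", call. = FALSE)
  exp(mean(log(ranks)))
}

#' Random-annotation baseline
#'
#' Expected top-k identification percentage when each experimental spectrum
#' is annotated with a uniformly random entry from its candidate set of size
#' \eqn{n_i}: \eqn{100 \cdot \mathrm{mean}_i(\min(k, n_i)/n_i)}. A
#' Monte-Carlo mode draws actual annotations with an explicit seed.
#'
#' @param candidate_counts Vector of per-record candidate-set sizes (>= 1).
#' @param k Top-k cutoff (>= 1).
#' @param method `"analytic"` (default) or `"monte-carlo"`.
#' @param draws Monte-Carlo repetitions of the whole validation set.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return Expected percentage of correct identifications.
#' @export
#' @examples
#' random_baseline(c(2, 4), k = 1) # 37.5
random_baseline <- function(candidate_counts, k,
                            method = c("analytic", "monte-carlo"),
                            draws = 1e5, seed = 1) {
  method <- match.arg(method)
  stopifnot(all(candidate_counts >= 1))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (method == "analytic") {
    return(100 * mean(pmin(k, candidate_counts) / candidate_counts))
  }
  p <- pmin(k, candidate_counts) / candidate_counts
  hits <- with_seed(seed, {
    vapply(p, function(pi) stats::rbinom(1, as.integer(draws), pi),
           numeric(1))
  })
  100 * sum(hits) / (draws * length(p))
}

#' Mean structural similarity per rank
#'
#' After an unsupervised search for each record, the mean Tanimoto
#' similarity between the true molecule and the molecule at each rank is
#' profiled, with the true molecule removed from every ranked list before
#' indexing. A decreasing profile shows that spectral similarity tracks
#' structural similarity.
#'
#' @param records Validation records tibble.
#' @param lib `ir_library`.
#' @param max_rank Deepest rank profiled; truncated (with a warning) to the
#'   smallest candidate-list size.
#' @param energy_tol Energy tolerance for the searches.
#' @return Tibble with columns `rank`, `mean_similarity`.
#' @export
similarity_vs_rank <- function(records, lib, max_rank = 50, energy_tol = 0) {
  sim <- similarity_matrix(lib$molecules)
  per_record <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    hits <- search_library(lib, r$spectrum[[1]], r$adduct,
                           mode = "unsupervised", energy_tol = energy_tol)
    others <- hits$molecule_id[hits$molecule_id != r$molecule_id]
    sim[r$molecule_id, others]
  })
  shortest <- min(lengths(per_record))
  if (max_rank > shortest) {
    warning("max_rank ", max_rank, " exceeds smallest candidate list (",
            shortest, "); truncating")
    max_rank <- shortest
  }
  tibble::tibble(
    rank = seq_len(max_rank),
    mean_similarity = vapply(seq_len(max_rank), function(r) {
      mean(vapply(per_record, `[`, numeric(1), r))
    }, numeric(1))
  )
}

#' Full retrieval evaluation report
#'
#' Convenience wrapper running the isomer and unsupervised searches (single
#' and combined adducts), the top-k curves, rank products, the analytic
#' random baseline and the similarity-vs-rank profile in one call.
#'
#' @param records Validation records tibble.
#' @param lib `ir_library`.
#' @param k_max Top-k curve depth.
#' @param max_rank Similarity-profile depth.
#' @param energy_tol Energy tolerance for all searches.
#' @return Object of class `iris_eval`: a list of per-mode rank tables
#'   (`ranks`), top-k curves (`topk`), rank products (`rank_products`),
#'   baseline curves (`baseline`) and the similarity profile
#'   (`similarity_profile`).
#' @export
evaluation_report <- function(records, lib, k_max = 10, max_rank = 50,
                              energy_tol = 0) {
  modes <- list(
    isomer = list(mode = "isomer", combine = FALSE),
    isomer_combined = list(mode = "isomer", combine = TRUE),
    unsupervised = list(mode = "unsupervised", combine = FALSE),
    unsupervised_combined = list(mode = "unsupervised", combine = TRUE)
  )
  ranks <- lapply(modes, function(m) {
    rank_records(records, lib, mode = m$mode, combine = m$combine,
                 energy_tol = energy_tol)
  })
  topk <- lapply(ranks, function(r) topk_curve(ranks = r, k_max = k_max))
  rp <- vapply(ranks, function(r) rank_product(r$rank), numeric(1))
  baseline <- lapply(ranks[c("isomer", "unsupervised")], function(r) {
    tibble::tibble(
      k = seq_len(k_max),
      percent = vapply(seq_len(k_max), function(k) {
        random_baseline(r$n_candidates, k)
      }, numeric(1))
    )
  })
  simprof <- suppressWarnings(
    similarity_vs_rank(records, lib, max_rank = max_rank,
                       energy_tol = energy_tol)
  )
  structure(
    list(ranks = ranks, topk = topk, rank_products = rp,
         baseline = baseline, similarity_profile = simprof,
         n_records = nrow(records),
         n_metabolites = length(unique(records$metabolite_id))),
    class = "iris_eval"
  )
}

#' @export
print.iris_eval <- function(x, ...) {
  cat("<iris_eval> ", x$n_records, " records / ", x$n_metabolites,
      " metabolites\n", sep = "")
  top1 <- vapply(x$topk, function(t) t$percent[1], numeric(1))
  for (m in names(top1)) {
    cat(sprintf("  %-22s top-1 %5.1f%%   RP %.2f\n", m, top1[[m]],
                x$rank_products[[m]]))
  }
  invisible(x)
}
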