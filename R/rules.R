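#' Convert a categorical data frame to transactions
#'
#' Each row becomes an item set of `"column=value"` strings. Numeric columns
#' with many levels are first equal-frequency binned with [discretize_ef()]
#' (the same discretization the feature-selection stage uses), so both stages
#' share one item universe. `NA` values contribute no item.
#'
#' @param data tibble of categorical / numeric columns.
#' @param bins bins for continuous columns (default 4).
#' @return list of character vectors (one per row).
#' @export
as_transactions <- function(data, bins = 4) {
  enc <- purrr::imap(data, function(v, nm) {
    if (is.numeric(v) && length(unique(stats::na.omit(v))) > bins) {
      v <- paste0("bin", discretize_ef(v, bins))
      v[v == "binNA"] <- NA
    }
    ifelse(is.na(v), NA_character_, paste0(nm, "=", v))
  })
  m <- do.call(cbind, enc)
  lapply(seq_len(nrow(m)), function(i) unname(m[i, !is.na(m[i, ])]))
}

itemset_support <- function(tmat, items) {
  if (length(items) == 1L) return(mean(tmat[, items]))
  mean(rowSums(tmat[, items, drop = FALSE]) == length(items))
}

#' Mine association rules for a target class
#'
#' Apriori level-wise frequent-itemset search with downward-closure pruning
#' (support anti-monotonicity is asserted at every level), followed by rule
#' construction restricted to rules whose consequent is one of the target
#' items. Rule length (antecedent plus consequent) is capped, mirroring the
#' at-most-six / at-least-90%-confidence protocol. Rules are ranked by lift
#' descending, with ties broken by confidence, support, then the antecedent
#' label.
#'
#' @param transactions list of character item sets (see [as_transactions()]).
#' @param consequent character vector of target items (e.g.
#'   `c("anxiety=1", "anxiety=0")`).
#' @param min_support minimum itemset support, > 0 (default 0.05).
#' @param min_confidence minimum rule confidence (default 0.9).
#' @param max_len maximum rule length including the consequent (default 6).
#' @return a `rule_set` tibble: `antecedent` (list-column), `consequent`,
#'   `support`, `confidence`, `lift`, `length`.
#' @export
mine_rules <- function(transactions, consequent,
                       min_support = 0.05, min_confidence = 0.9,
                       max_len = 6) {
  if (min_support <= 0) stop("mine_rules(): min_support must be > 0")
  universe <- sort(unique(unlist(transactions)))
  if (!any(consequent %in% universe)) {
    stop("mine_rules(): no target item present in the transactions")
  }
  n <- length(transactions)
  tmat <- matrix(FALSE, n, length(universe), dimnames = list(NULL, universe))
  for (i in seq_len(n)) tmat[i, transactions[[i]]] <- TRUE

  supp <- new.env(parent = emptyenv())
  key <- function(items) paste(items, collapse = "\r")

  level <- lapply(universe, identity)
  freq_by_level <- list()
  k <- 1L
  repeat {
    keep <- list()
    for (items in level) {
      s <- itemset_support(tmat, items)
      if (k > 1L) {
        # downward closure: support can never exceed any subset's support
        sub_supp <- vapply(seq_along(items), function(d) {
          get(key(items[-d]), envir = supp)
        }, numeric(1))
        stopifnot(s <= min(sub_supp) + 1e-12)
      }
      if (s >= min_support) {
        assign(key(items), s, envir = supp)
        keep[[length(keep) + 1L]] <- items
      }
    }
    if (!length(keep) || k == max_len) {
      freq_by_level[[k]] <- keep
      break
    }
    freq_by_level[[k]] <- keep
    # candidate generation: join sets sharing their first k-1 items, then
    # prune candidates with any infrequent k-subset
    cand <- list()
    if (length(keep) >= 2L) {
      prefixes <- vapply(keep, function(x) key(x[-length(x)]), character(1))
      lasts <- vapply(keep, function(x) x[length(x)], character(1))
      for (p in unique(prefixes)) {
        grp <- which(prefixes == p)
        if (length(grp) < 2L) next
        for (a in seq_along(grp)) for (b in seq_along(grp)) {
          if (lasts[grp[a]] < lasts[grp[b]]) {
            items <- c(keep[[grp[a]]], lasts[grp[b]])
            all_freq <- all(vapply(seq_along(items), function(d) {
              exists(key(items[-d]), envir = supp)
            }, logical(1)))
            if (all_freq) cand[[length(cand) + 1L]] <- items
          }
        }
      }
    }
    if (!length(cand)) break
    level <- cand
    k <- k + 1L
  }

  frequent <- unlist(freq_by_level, recursive = FALSE)
  rules <- purrr::map_dfr(frequent, function(items) {
    tgt <- intersect(items, consequent)
    if (length(tgt) != 1L || length(items) < 2L) return(NULL)
    ante <- setdiff(items, tgt)
    if (any(ante %in% consequent)) return(NULL)
    s_rule <- get(key(items), envir = supp)
    s_ante <- get(key(ante), envir = supp)
    conf <- s_rule / s_ante
    if (conf < min_confidence) return(NULL)
    s_cons <- itemset_support(tmat, tgt)
    tibble(antecedent = list(ante), consequent = tgt,
           support = s_rule, confidence = conf, lift = conf / s_cons,
           length = length(items))
  })
  if (is.null(rules) || nrow(rules) == 0L) {
    rules <- tibble(antecedent = list(), consequent = character(),
                    support = numeric(), confidence = numeric(),
                    lift = numeric(), length = integer())
  } else {
    akey <- vapply(rules$antecedent, paste, character(1), collapse = ",")
    rules <- rules[order(-rules$lift, -rules$confidence, -rules$support,
                         akey), ]
  }
  class(rules) <- c("rule_set", class(rules))
  rules
}

#' Build a co-occurrence network from mined rules
#'
#' Nodes are the antecedent items of the retained (optionally top-lift)
#' rules, sized by the number of rules they occur in; an edge joins two items
#' that co-occur in at least one rule's antecedent, weighted by the
#' co-occurrence count and carrying the mean lift of the shared rules.
#'
#' @param rules a `rule_set`.
#' @param top_n keep only the `top_n` highest-lift rules (default all).
#' @return a `rule_network` list: `graph` (igraph), `nodes`, `edges` tibbles.
#' @export
rule_network <- function(rules, top_n = Inf) {
  rules <- utils::head(rules, top_n)
  if (nrow(rules) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    out <- list(graph = g,
                nodes = tibble(item = character(), freq = integer()),
                edges = tibble(item1 = character(), item2 = character(),
                               count = integer(), mean_lift = numeric()))
    class(out) <- "rule_network"
    return(out)
  }
  nodes <- tibble(item = unlist(rules$antecedent)) |>
    dplyr::count(.data$item, name = "freq") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$item)
  edges <- purrr::map2_dfr(rules$antecedent, rules$lift, function(a, l) {
    if (length(a) < 2L) return(NULL)
    prs <- utils::combn(sort(a), 2)
    tibble(item1 = prs[1, ], item2 = prs[2, ], lift = l)
  })
  edges <- if (nrow(edges)) {
    edges |>
      dplyr::group_by(.data$item1, .data$item2) |>
      dplyr::summarise(count = dplyr::n(), mean_lift = mean(.data$lift),
                       .groups = "drop")
  } else {
    tibble(item1 = character(), item2 = character(), count = integer(),
           mean_lift = numeric())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  out <- list(graph = g, nodes = nodes, edges = edges)
  class(out) <- "rule_network"
  out
}

#' Sex-stratified rule networks
#'
#' Builds one co-occurrence network per stratum from a named list of rule
#' sets mined separately within each stratum (e.g. males and females).
#'
#' @param rules_by_stratum named list of `rule_set` tibbles.
#' @param top_n top-lift rules per stratum fed to each network.
#' @return named list of `rule_network` objects.
#' @export
stratified_networks <- function(rules_by_stratum, top_n = Inf) {
  purrr::map(rules_by_stratum, rule_network, top_n = top_n)
}

#' Write a rule set to TSV
#'
#' Columns: antecedent (comma-joined), consequent, support, confidence,
#' lift.
#'
#' @param rules a `rule_set`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rules_tsv <- function(rules, path) {
  flat <- dplyr::mutate(rules, antecedent = vapply(.data$antecedent, paste,
                                                   character(1),
                                                   collapse = ","))
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
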