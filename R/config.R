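# Global configuration: one nested list controlling the codec, channel,
# thresholds and budgets, serializable to YAML for the command-line driver.

#' Default pipeline configuration
#'
#' @param K segment count (filled in from the input file at encode time when
#'   `NULL`).
#' @return nested list with sections `code`, `constraints`, `simulate`,
#'   `analysis`.
#' @export
default_config <- function(K = NULL) {
  list(
    code = list(K = K, c = 0.025, delta = 0.001,
                rs = list(n = 38L, k = 36L, prim = 285L, fcr = 0L)),
    constraints = list(max_run = 3L, gc_min = 45, gc_max = 55,
                       screened_region = "seed_plus_payload"),
    simulate = list(pf_fraction = 0.894, adapter_tail_fraction = 0),
    analysis = list(tau_e = 5L, tau_adj = 4L,
                    cap_sub = NA, cap_del = NA, cap_ins = NA,
                    l_origin = 152L, target_window = c(145L, 153L),
                    max_null = 128L, max_bit = 1024L, max_split = 20L)
  )
}

#' Read a YAML configuration file
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  def <- default_config()
  merge_lists <- function(d, u) {
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]))
        merge_lists(d[[k]], u[[k]]) else u[[k]]
    }
    d
  }
  merge_lists(def, usr)
}

# materialize the typed parameter objects from a config list
config_objects <- function(cfg) {
  list(
    lt = if (!is.null(cfg$code$K))
      lt_config(cfg$code$K, cfg$code$c, cfg$code$delta) else NULL,
    rs = rs_params(cfg$code$rs$n, cfg$code$rs$k, cfg$code$rs$prim,
                   cfg$code$rs$fcr),
    spec = constraint_spec(cfg$constraints$max_run, cfg$constraints$gc_min,
                           cfg$constraints$gc_max,
                           cfg$constraints$screened_region),
    thresholds = cluster_thresholds(cfg$analysis$tau_e, cfg$analysis$tau_adj,
                                    cfg$analysis$cap_sub, cfg$analysis$cap_del,
                                    cfg$analysis$cap_ins),
    budgets = list(max_null = cfg$analysis$max_null,
                   max_bit = cfg$analysis$max_bit,
                   max_split = cfg$analysis$max_split)
  )
}
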