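# Shared fixtures: small synthetic cell-assembly tables and rasters built
# in code.

# balanced synthetic CA table: n_networks x (2 categories x words) x areas
make_ca_table <- function(n_networks = 12, words_per_cat = 6,
                          areas = area_table()$area, effect = NULL,
                          seed = 1) {
  set.seed(seed)
  grid <- expand.grid(network_id = seq_len(n_networks),
                      word_id = seq_len(2 * words_per_cat) - 1L,
                      area = areas, stringsAsFactors = FALSE)
  grid$category <- ifelse(grid$word_id < words_per_cat, "object", "action")
  mu <- 20 + 5 * rnorm(1)
  grid$ca_count <- pmax(0, round(mu + rnorm(nrow(grid), sd = 4)))
  if (!is.null(effect)) {
    sel <- grid$category == "action" & grid$area == effect$area
    grid$ca_count[sel] <- grid$ca_count[sel] + effect$shift
  }
  grid$ca_count <- pmin(grid$ca_count, 625L)
  ca_table(grid[, c("network_id", "word_id", "category", "area",
                    "ca_count")])
}

# synthetic raster with prescribed spikes: `hits` is a data.frame with
# columns step, cell (1-based global index)
make_raster <- function(n_steps, areas = c("X", "Y"), n_exc = 25L,
                        hits = NULL) {
  r <- matrix(0L, nrow = n_steps, ncol = length(areas) * n_exc)
  if (!is.null(hits)) r[cbind(hits$step, hits$cell)] <- 1L
  structure(r, class = c("spike_raster", "matrix"), areas = areas,
            n_exc = n_exc)
}

# independent repeated-measures ANOVA oracle via stats::aov error strata
aov_oracle <- function(table) {
  agg <- stats::aggregate(ca_count ~ network_id + category + area,
                          data = table, FUN = mean)
  agg$network_id <- factor(agg$network_id)
  agg$category <- factor(agg$category)
  agg$area <- factor(agg$area)
  fit <- stats::aov(ca_count ~ category * area +
                      Error(network_id / (category * area)), data = agg)
  s <- summary(fit)
  grab <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    tab[row, c("F value", "Pr(>F)")]
  }
  list(wordtype = grab("Error: network_id:category", "category"),
       area = grab("Error: network_id:area", "area"),
       interaction = grab("Error: network_id:category:area",
                          "category:area"))
}
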