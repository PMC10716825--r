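# mlcps

Ranking trained classifiers from a panel of evaluation metrics — accuracy,
precision, recall, F1, average precision, ROC AUC, … — is error-prone when
done by eye: each metric measures a different aspect of performance and the
columns rarely agree. `mlcps` collapses one model's metric panel into a
single **cumulative performance score**: the metric values
$d_1, \dots, d_n$ are drawn as equally spaced rays on a polar plane
($\theta = 2\pi/n$ between adjacent rays) and the score is the area of the
closed polygon joining the ray tips,

$$
\mathrm{CPS} = \frac{1}{2}\sin\theta \sum_{i=1}^{n} d_i d_{i+1},
\qquad d_{n+1} \equiv d_1 .
$$

The score is strictly monotone in every metric, scales quadratically under
a common rescaling, rewards panels that are both *high* and *balanced*, and
supports non-negative per-metric weights (weight 0 excludes a metric and
shrinks the polygon). It is aimed at anyone — e.g. in biomedical
classification, where imbalanced omics datasets make single-metric model
selection treacherous — who needs a defensible, automatic model ranking.

The package provides:

* `compute_mlcps()` / `compute_mlcps_table()` — the score for one metric
  vector or a whole models × metrics table (shared ray ordering);
* `metric_panel()` + `prediction_set()` — the standard binary-classification
  metric panel from labels and scores, with loud errors instead of silent
  `NaN`s;
* `compare_rankings()` — score ranking with a metric-SD consistency
  baseline and optional train/test rank-agreement report;
* `simulate_classifier()` / `make_metric_table()` — synthetic inputs with
  known ground truth;
* `read_metrics_table()`, `read_weights()`, `read_predictions()` and
  friends — strict CSV/TSV and JSON/YAML IO;
* `render_plot()` — radar, ranked-bar and SD-vs-score plots;
* a command line (`inst/cli/mlcps`) wrapping the above.

## Worked example

Score three simulated classifiers — a weak one, a strong one, and a
constant "always positive" dummy — on a five-metric panel:

```r
library(mlcps)

weak   <- simulate_classifier(5000, separation = 1, seed = 42)
strong <- simulate_classifier(5000, separation = 3, seed = 42)
dummy  <- prediction_set(weak$y_true, rep(1, 5000), rep(0.5, 5000))

panel <- c("accuracy", "recall", "f1", "average_precision", "roc_auc")
m <- rbind(weak   = metric_panel(weak, panel),
           strong = metric_panel(strong, panel),
           dummy  = metric_panel(dummy, panel))
compare_rankings(metrics_table(m))
```

```
Cumulative performance score ranking (3 models, 5 rays, angle 1.2566 rad)
Ray order: accuracy > recall > f1 > average_precision > roc_auc

  model  mlcps mlcps_normalized     sd rank_mlcps rank_sd tie_mlcps
 strong 2.1581           0.9076 0.0286          1       1     FALSE
   weak 1.2553           0.5280 0.0341          2       2     FALSE
  dummy 0.9609           0.4042 0.2159          3       3     FALSE
```

`mlcps` is the polygon area (at most $\tfrac{5}{2}\sin(2\pi/5) \approx
2.378$ for five metrics on $[0,1]$; `mlcps_normalized` divides by that
maximum). The strong classifier's polygon is largest, rank 1. The dummy
scores 0.96 despite a perfect recall of 1.0 — its other rays are short, and
the large metric SD (0.216) flags exactly the imbalance the score
penalises. The same analysis from the shell:

```sh
Rscript inst/cli/mlcps panel --predictions weak.csv strong.csv --out table.csv
Rscript inst/cli/mlcps score --metrics table.csv --out report.csv --plot bar:scores.png
```

Weights come from a JSON/YAML file, e.g. `{"f1": 2, "accuracy": 0}` doubles
the F1 ray and removes accuracy from the polygon entirely.

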