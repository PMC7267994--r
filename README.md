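# cpigcn

Sentence-level **chemical-protein interaction (CPI) extraction** in the
ChemProt / BioCreative VI setting, for text-mining and drug-discovery
pipelines that need structured chemical-gene relations out of abstracts.

Given a chemical mention and a gene/protein mention in one sentence, the
model assigns one of the five evaluated ChemProt relation groups — CPR:3
(up-regulation), CPR:4 (down-regulation), CPR:5 (agonist), CPR:6
(antagonist), CPR:9 (substrate/product) — or NEG (no relation). The scoring
function is a bidirectional LSTM over the whole sentence followed by an
*L*-layer graph convolutional network (GCN) over the dependency tree,
**path-centrically pruned**: only tokens within tree-distance *N* of the
dependency path between the two mentions (inside their LCA subtree) keep
their edges. Each GCN layer computes

```
h_i^(l) = ReLU( sum_j  A~_ij  W^(l) h_j^(l-1) / d_i  +  b^(l) ),   A~ = A + I
```

with degree normalization `d_i = sum_j A~_ij` and self-loops. Sentence and
entity representations (`h_sent`, `h_c`, `h_p`) are element-wise max-pools,
concatenated into a feed-forward layer and a softmax over the six classes.
Evaluation is micro-averaged precision/recall/F over exact
(document, Arg1, Arg2, class) tuples.

The package also provides:

* readers/writers for the ChemProt three-file TSV corpus format
  (abstracts / entities / relations) and 4-column prediction files;
* preprocessing: sentence splitting with mention-aware boundary repair,
  candidate-pair generation, digit normalization (`"50"` → `"num"` outside
  entity mentions), entity-type tagging, CoNLL-U parse attachment, and the
  deterministic 9:1 document-level re-split;
* dependency-tree algorithms (LCA, dependency path, pruning, adjacency)
  validated against brute-force oracles;
* a full training loop (SGD, learning rate 0.3, dropout 0.5, gradient-norm
  clipping), sweeps over pruning distance and embedding features, and a
  **synthetic ChemProt-format corpus generator** with plantable trigger-word
  signal so everything is testable offline.

All neural forward/backward passes (including LSTM BPTT) are implemented in
base R and verified against finite differences — no deep-learning framework
is required. See the methods vignette (`vignettes/cpi-gcn-methods.Rmd`) for
the model, the design decisions and what the synthetic tests do and do not
establish.

## Worked example

```r
library(cpigcn)

# a synthetic ChemProt-format corpus: TSV files + CoNLL-U parses + manifest
sim <- generate_corpus(sim_spec(n_documents = 200, seed = 42),
                       dir = file.path(tempdir(), "demo"))
corpus <- read_corpus(sim$paths$abstracts, sim$paths$entities,
                      sim$paths$relations)
corpus
#> <chemprot_corpus> 200 documents, 2136 entity mentions, 700 relations (700 evaluated)

examples <- prepare_examples(corpus, sim$paths$conllu)
examples
#> <cpi_examples> 1124 candidate pairs (CPR:3=140, CPR:4=138, CPR:5=132, CPR:6=146, CPR:9=144, NEG=424)

halves <- resplit(examples, split_spec(seed = 42))        # 9:1 by document
config <- model_config(word_dim = 32, pos_dim = 8, etype_dim = 8,
                       lstm_hidden = 32, gcn_hidden = 32, ffnn_hidden = 32,
                       gcn_layers = 2, prune_dist = 2)
model <- train_cpi(halves$train, halves$dev, config,
                   train_spec(max_epochs = 20, seed = 42))
model
#> <cpi_model> 20 epoch(s) trained; best dev F 100.00% at epoch 15

preds <- predict(model, halves$dev)
head(preds, 3)
#>   doc_id cpr_group arg1_id arg2_id
#> 1  D0007     CPR:9      T1      T2
#> 2  D0007     CPR:3      T5      T6
#> 3  D0007     CPR:5      T7      T8
micro_f(gold_relations(halves$dev), preds)
#> micro P 100.00%  R 100.00%  F 100.00%  (TP 65, FP 0, FN 0)
```

The held-out micro-F near 100% reflects the synthetic corpus's construction
— each positive pair's class is recoverable from a trigger token — so it
validates the implementation, not biomedical performance.

Pruning on the appositive template (trigger off the bare path, distractor
clause at distance 3):

```r
u <- generate_unit_tree("appositive_distractor")
prune(u$tree, u$chem_span, u$prot_span, 0)   # bare path: no trigger
#> [1] 1 7 8
prune(u$tree, u$chem_span, u$prot_span, 2)   # keeps trigger, drops distractor
#>  [1]  1  2  3  4  5  6  7  8  9 10 11 14 15
```

## Command line

```sh
alias cpigcn="Rscript inst/cli/cpigcn"
cpigcn simulate --out corpus/ --n-documents 200 --seed 42
cpigcn preprocess --corpus-dir corpus/ --out examples.jsonl
cpigcn train --corpus-dir corpus/ --out model.rds --epochs 20
cpigcn predict --model model.rds --corpus-dir corpus/ --out preds.tsv
cpigcn evaluate --corpus-dir corpus/ --pred preds.tsv
cpigcn sweep --corpus-dir corpus/ --prune-dists 0,2
cpigcn prune --conllu corpus/parses.conllu --doc D0001 --sent 2 \
    --chem 1 --prot 8 --N 2
```

Model configuration files use DCF syntax with fields named after the
`model_config()` arguments (`word_dim: 200`, `prune_dist: 2`, ...); `train`
writes a `<model>.log` with the seed, configuration and per-epoch metrics.

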