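# scattn — sparse-attention cell type annotation for scRNA-seq

`scattn` annotates cell types in single-cell RNA-seq count matrices with a
sparse cross-attention set encoder. Instead of restricting the input to a
few thousand highly variable genes — which loses information and makes the
feature set dataset-dependent — every gene keeps a learned embedding, and
each cell is encoded **only through the genes it actually expresses**. The
package is for analysts who need fast, CPU-scale annotation of query
datasets against a labeled reference, latent representations for
clustering or trajectory export, and an interpretable per-cluster ranking
of the genes the model relied on.

## The model

For cell *i*, the non-zero gene indices and values are extracted and the
values mean-scaled (divided by the mean non-zero value, so they average
1). Each expressed gene contributes its embedding row scaled by the cell's
value, `v_ij · e_gj`. A trainable CLS vector aggregates this set through
N multi-head cross-attention blocks:

```
hidden_h = softmax(Q_h K_hᵀ / d) V_h          Q = X_q W_h^Q,  K = V = from gene embeddings
O  = X_q + LayerNorm(Concat(hidden_1..H) W^O)
Z  = O  + LayerNorm(FFN(O))
```

Block 1 queries with CLS; later blocks query with the previous output. The
final `Z` row is the cell's latent representation. Gene embeddings are
initialized by PCA on the gene-by-cell matrix, refined by contrastive
pre-training (NT-Xent, τ = 0.1, 15% random gene masking for the augmented
view), and fine-tuned with a softmax classifier under cross-entropy.
Attention weights (final block, head-averaged) summed per predicted
cluster, `w_jk = Σ_{i∈C_k} attn_ij`, rank *critical genes* — candidate
markers per cluster — with a permutation test for marker-set rank
enrichment. Padded batch slots are masked out of every softmax, so results
are independent of batch composition.

Evaluation helpers cover accuracy, macro F1, ARI, NMI, average silhouette
width, cell-type ASW `(ASW+1)/2` and batch ASW (absolute silhouette on
batch labels within each cell type, averaged as `1 − |s|`). A
splatter-style count simulator with planted exclusive markers and a
library-size depth dial (`lib_loc`) provides ground-truth benchmarks.

## Worked example

```r
library(scattn)

sim   <- make_fixture("tiny")            # 40 cells x 50 genes, 2 groups
x     <- sim$data
vocab <- build_vocabulary(x)
emb   <- pca_init(x, vocab, D = 16, n_sample = 40, seed = 1)
model <- init_model(vocab, model_config(D = 16, H = 2, N = 2,
                                        F_hidden = 32, P = 16),
                    embedding = emb, seed = 1)
model <- pretrain(model, x, contrastive_config(epochs = 1, batch_size = 16, seed = 1))
model <- finetune(model, x, train_config(epochs = 10, batch_size = 16, seed = 1))

ann <- annotate(model, x, capture_attention = TRUE)
accuracy_f1(x$labels, ann$predictions$predicted_label)
#> $accuracy
#> [1] 1
#> $f1_macro
#> [1] 1

head(critical_genes(ann$attention,
                    ann$predictions$predicted_label[ann$kept],
                    vocab, top_k = 3))
#>   cluster rank gene_symbol    weight
#> 1  Group1    1       G0049 2.7575032
#> 2  Group1    2       G0020 2.1540707
#> 3  Group1    3       G0047 1.1031977
#> 4  Group2    1       G0002 1.0949024
#> 5  Group2    2       G0005 0.9225767
#> 6  Group2    3       G0019 0.8897129
```

Training labels are recovered perfectly on this separable toy, and the
top-ranked critical genes are planted markers of their clusters (Group1's
markers include G0049, G0020, G0047; Group2's include G0002 and G0019).
The `weight` column is summed attention: Group1's 21 cells spend ~2.76 of
their total attention mass on G0049.

A command-line interface wraps the same pipeline:

```sh
scattn simulate --fixture tiny --out data/ --seed 1
scattn pretrain --ref data/ --out pre.rds  --preset short --seed 1
scattn finetune --model pre.rds --ref data/ --out fit.rds --preset short --seed 1
scattn annotate --model fit.rds --query data/ --out predictions.tsv
scattn evaluate --true data/labels.tsv --pred predictions.tsv --out metrics.tsv
```

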