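# Demo pipeline configuration: two young families in a 60 kb background.
# Run with: inst/cli/retro-chrono run --config inst/extdata/demo.cfg --out out/
seed = 5
out_dir = retrochrono_demo
stages = simulate,detect,classify,cluster,date,tree,depth
background_length = 60000
n_families = 2
copy_min = 2
copy_max = 3
ltr_length = 400
internal_length = 3000
age_min_my = 0
age_max_my = 1
coverage = 5
read_length = 100
error_rate = 0
top_n = 20
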