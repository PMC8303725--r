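# Full synthetic end-to-end demonstration run.
stage: demo
seed: 1
outdir: demo_out
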