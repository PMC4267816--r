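{
  "package": "fmnet",
  "version": "1.0.0",
  "config_md5": null,
  "files": []
}
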