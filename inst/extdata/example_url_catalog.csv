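domain,category,provenance
critical1.example,vaccine_critical,seed
critical2.example,vaccine_critical,seed
critical3.example,vaccine_critical,seed
critical4.example,vaccine_critical,seed
media1.example,media,seed
media2.example,media,seed
media3.example,media,seed
media4.example,media,seed
media5.example,media,seed
media6.example,media,seed
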