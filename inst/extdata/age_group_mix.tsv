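age_group	cancer	normal
20-30	147	683
31-40	381	685
41-50	711	734
51-60	805	740
61-70	558	556
>70	229	216
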