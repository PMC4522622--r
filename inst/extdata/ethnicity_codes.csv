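code,group
White British,White
White Irish,White
Any other White background,White
Mixed White and Black Caribbean,Black
Mixed White and Black African,Black
Mixed White and Asian,Asian
Any other Mixed background,White
Indian,Asian
Pakistani,Asian
Bangladeshi,Asian
Any other Asian background,Asian
Black Caribbean,Black
Black African,Black
Any other Black background,Black
Chinese,White
Any other ethnic group,White
Asian,Asian
Black,Black
White,White
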