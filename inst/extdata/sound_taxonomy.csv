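"exemplar","subordinate","intermediate","superordinate"
"baby","mouth sounds","humans","animate"
"cough","mouth sounds","humans","animate"
"talking","mouth sounds","humans","animate"
"walking with heels","feet sounds","humans","animate"
"walking on gravel","feet sounds","humans","animate"
"marching","feet sounds","humans","animate"
"person clapping","hand sounds","humans","animate"
"audience applause","hand sounds","humans","animate"
"snapping fingers","hand sounds","humans","animate"
"dog","mammals","animals","animate"
"sheep","mammals","animals","animate"
"horse","mammals","animals","animate"
"chicken","birds","animals","animate"
"duck","birds","animals","animate"
"seagull","birds","animals","animate"
"bee","insects","animals","animate"
"cricket","insects","animals","animate"
"mosquito","insects","animals","animate"
"bike","by road","vehicles","inanimate"
"car","by road","vehicles","inanimate"
"motorbike","by road","vehicles","inanimate"
"helicopter","by air","vehicles","inanimate"
"plane","by air","vehicles","inanimate"
"jet","by air","vehicles","inanimate"
"ferry","by sea","vehicles","inanimate"
"tugboat","by sea","vehicles","inanimate"
"jetski","by sea","vehicles","inanimate"
"drill","tools","objects","inanimate"
"hammer","tools","objects","inanimate"
"handsaw","tools","objects","inanimate"
"microwave","kitchen","objects","inanimate"
"teaspoon","kitchen","objects","inanimate"
"soda can","kitchen","objects","inanimate"
"phone","office","objects","inanimate"
"scissors","office","objects","inanimate"
"typewriter","office","objects","inanimate"
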