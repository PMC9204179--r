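# Spam keyword lexicon: posts whose text contains any of these phrases on
# word boundaries (case-insensitive) are treated as non-patient content.
online store
online pharmacy
press release
discount code
promo code
coupon code
free shipping
buy now
click here
limited time offer
best price
order today
visit our website
subscribe now
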